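# uwcager

Relative age estimation for neonatal viviparous sharks from the size of
their healing umbilical wound.

Neonates of live-bearing sharks are born with an open umbilical wound that
closes over the first weeks of life. Because the wound shrinks at a
predictable rate, its size is a non-lethal clock: measuring the wound at a
single capture tells you approximately how many days ago the animal was
born. Field programmes have long exploited this with coarse, subjective
"umbilical wound classes" (open / partly healed / healed); `uwcager`
implements the quantitative version — regression-calibrated class
boundaries, per-capture age estimates, and the downstream analyses they
enable (validation against recapture intervals, parturition-season
back-calculation, body-condition trends). It is written for quantitative
ecologists working with mark-recapture records of neonatal sharks, and
ships a cohort simulator so every stage can be exercised and tested without
field data.

## The model

Two healing regressions are fitted to recaptured *days-old* neonates —
animals first caught while still bearing umbilical-cord remnants, which are
shed within a couple of days of birth and therefore anchor the animal's age
at ~0:

- wound area (cm²), after square-root transformation, declines linearly in
  the square root of age *t* (days):
  `sqrt(A) = a0 − a1·sqrt(t)`, i.e. a quadratic decline
  `A(t) = (a0 − a1·sqrt(t))²`;
- wound perimeter (cm) declines linearly: `P(t) = b0 − b1·t`.

Both are linear mixed-effects models with a per-shark random intercept
(repeated measures), fitted by REML via `lme4`. With the reference
coefficients `(a0, a1, b0, b1) = (0.311, 0.053, 1.299, 0.037)` the curves
reach zero at 34.4 d (area) and 35.1 d (perimeter), so wounds close
completely by day 36. Evaluating the curves at 12 and 24 days gives the
critical sizes `A* = 0.016 cm²` and `P* = 0.41 cm` that define four
umbilical wound classes (UWCs):

| UWC | age (days) | area (cm²) | perimeter (cm) |
|-----|-----------|------------|----------------|
| 1   | 0–12      | > 0.016    | > 0.41         |
| 2   | 12–24     | ≤ 0.016    | > 0.41         |
| 3   | 24–36     | < 0.016    | ≤ 0.41         |
| 4   | ≥ 36      | 0          | 0              |

Perimeter decides first (it separates UWC2 from UWC3, where area
overlaps), then area separates UWC1 from UWC2. Inverting the curves gives
per-capture ages, `t_A = ((a0 − sqrt(A))/a1)²` and `t_P = (b0 − P)/b1`
(clamped at zero on the physical branch), whose mean is the combined age
estimate. The scheme is validated by comparing predicted vs actual time at
liberty (pTAL vs TAL) of recaptured sharks, parturition dates are
back-calculated by subtracting the class midpoint age (6 / 18 / 30 days)
from the first capture date, and body condition is tracked across classes
with Fulton's factor `K = 10⁵·M·PCL⁻³` (mass in kg, precaudal length in
cm) using Shapiro–Wilk screens, one-way ANOVA and Tukey HSD.

## Worked example

Simulate six-season-style survey data (800 field sharks plus 60 recaptured
days-old neonates for training) and run the full pipeline:

```r
library(uwcager)

cohort <- generate_cohort(synthetic_config(n_sharks = 800,
                                           n_training = 60, seed = 42))
bundle <- run_pipeline(cohort$events)
#> [uwcager] read: 1005 capture events, 860 sharks
#> [uwcager] training: 135 open-wound observations from 64 days-old anchored sharks (6 closed-wound obs excluded)
#> [uwcager] fit: area model by REML, perimeter model by OLS
#> [uwcager] scheme: crit area 0.017 cm^2, crit perimeter 0.35 cm, closure day 42
#> [uwcager] classify: counts 1=253, 2=230, 3=157, 4=365, unclassifiable=0
#> [uwcager] validate: 10 recapture pairs scored, 117 excluded
#> [uwcager] parturition: 550 estimates (310 juveniles skipped)

bundle$fit
#> <wound_model_fit>
#>   sqrt(area) = 0.3105 - 0.0482 sqrt(age)   [REML]
#>   perimeter  = 1.2364 - 0.0318 age         [OLS]
#>   variance components: id (1.03e-03, 0.00e+00), residual (1.38e-03, 7.28e-02)
#>   135 observations on 64 individuals
```

The fitted coefficients scatter around the generating values
(0.311, 0.053, 1.299, 0.037) as expected at this training-set size; the
derived scheme, the validation error, the parturition season and the
condition trend all follow:

```r
bundle$summary$validation
#> $mean_abs_diff 3.9   $sd_abs_diff 2.9   $n 10          # pTAL vs TAL, days

unlist(bundle$summary$month_histogram)
#> Aug Sep Oct Nov Dec Jan Feb
#>   6  57 186 202  89   8   2                # back-calculated parturitions

bundle$seasonality
#> chi2 = 257.2, df = 4, p < 0.001            # vs uniform over Sep-Jan

bundle$morphometrics$k$anova
#> F(3, 1001) = 78.99, p < 0.001              # Fulton's K declines with UWC
```

A shell interface wrapping the same functions lives in
`inst/scripts/uwcager.R` (subcommands `simulate`, `fit`, `classify`,
`validate`, `parturition`, `morpho`, `run`).

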