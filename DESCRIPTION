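Package: uwcager
Title: Quantitative Umbilical Wound Classification and Relative Age
    Estimation for Neonatal Viviparous Sharks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the relative age of neonatal viviparous sharks from
    the size of their healing umbilical wound. Fits mixed-effects healing
    regressions (square-root wound area against square-root age, wound
    perimeter against age) from recaptured days-old neonates, derives
    critical wound sizes that split the neonatal period into ordinal
    umbilical wound classes (UWCs), inverts the regressions to estimate
    per-capture age, validates the scheme by predicted versus actual time
    at liberty, back-calculates parturition dates to characterise the
    birth season, and compares morphometrics and Fulton's body condition
    across classes. Includes a mark-recapture cohort simulator with the
    statistical structure the analysis assumes, so the full pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
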