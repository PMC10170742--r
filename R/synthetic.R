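# Moorea-style site pool used for the optional `site` column
.site_pool <- c("Apaura", "Haapiti", "Maharepa", "Paorea", "Papetoai",
                "Pihaena", "Tiki", "Vaiane", "Vaiare", "Valorie")

#' Configuration for the mark-recapture cohort simulator
#'
#' Bundles every generator parameter. The defaults are the study
#' conditions the analysis assumes: healing-curve coefficients from the
#' fitted regressions (sqrt(area) = 0.311 - 0.053 sqrt(age); perimeter =
#' 1.299 - 0.037 age), a September-to-January multinomial birth season
#' peaking in October/November, neonatal precaudal length 41.7 +/- 2.0 cm,
#' and a recapture rate of about 8.5%. Measurement-noise SDs (on the
#' scales where the models are linear: sqrt-area and raw perimeter) are
#' calibrated so that the end-to-end predicted-vs-actual time-at-liberty
#' error on two-capture sharks is about 5 days, the scheme's validated
#' accuracy; see the package vignette for the calibration.
#'
#' @param a0,a1 sqrt-area model intercept (sqrt(cm^2)) and slope (per
#'   sqrt-day).
#' @param b0,b1 perimeter model intercept (cm) and slope (cm/day).
#' @param sigma_id_area,sigma_id_perim SDs of per-shark random intercepts
#'   (sqrt-area and perimeter scales).
#' @param sigma_eps_area,sigma_eps_perim measurement-noise SDs (same
#'   scales).
#' @param month_probs named probability vector over birth months, names
#'   `Sep, Oct, Nov, Dec, Jan` (or any consecutive run of month
#'   abbreviations); must sum to 1.
#' @param n_sharks number of field-cohort individuals (first capture at a
#'   uniform age in the capture window, recaptured with probability
#'   `recapture_prob`).
#' @param n_training number of "time-zero" training individuals: captured
#'   as days-old neonates (age 0, cord remnants attached) and recaptured
#'   at least once — the mark-recapture design from which the healing
#'   regressions are fit. The default 16 is the study condition.
#' @param second_recapture_prob probability a training shark is recaptured
#'   a second time (default 3/16, the observed share of twice-recaptured
#'   training animals).
#' @param recapture_prob per-shark probability of (each successive)
#'   recapture in the field cohort; capped at `max_recaptures`.
#' @param max_recaptures maximum recaptures per shark.
#' @param capture_window days post-birth during which first capture can
#'   occur (uniform integer age in `[0, capture_window]`).
#' @param cord_max_age age (days) up to which umbilical-cord remnants are
#'   still attached; events at or below it get `cord_remnants = TRUE`.
#' @param recapture_lag_range integer range of days between successive
#'   captures (sampling-night spacing).
#' @param pcl_birth_mean,pcl_birth_sd precaudal length at birth (cm).
#' @param pcl_growth_rate linear PCL growth (cm/day) over the first weeks.
#' @param k0 Fulton's K at age 0 (on the 1e5 kg cm^-3 scale).
#' @param k_slope change in K per day of age (negative: condition declines
#'   as in-utero reserves deplete).
#' @param k_sd individual noise SD on K.
#' @param season_start_year calendar year of the season's first month.
#' @param seed default RNG seed used by [generate_cohort()].
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(a0 = 0.311, a1 = 0.053,
                             b0 = 1.299, b1 = 0.037,
                             sigma_id_area = 0.03, sigma_id_perim = 0.08,
                             sigma_eps_area = 0.04, sigma_eps_perim = 0.26,
                             month_probs = c(Sep = 0.052, Oct = 0.327,
                                             Nov = 0.413, Dec = 0.176,
                                             Jan = 0.032),
                             n_sharks = 200,
                             n_training = 16,
                             second_recapture_prob = 3 / 16,
                             recapture_prob = 0.085,
                             max_recaptures = 2,
                             capture_window = 60,
                             cord_max_age = 2,
                             recapture_lag_range = c(7, 28),
                             pcl_birth_mean = 41.7, pcl_birth_sd = 2.0,
                             pcl_growth_rate = 0.033,
                             k0 = 1.25, k_slope = -0.2 / 60, k_sd = 0.1,
                             season_start_year = 2020,
                             seed = NULL) {
  cfg <- list(a0 = a0, a1 = a1, b0 = b0, b1 = b1,
              sigma_id_area = sigma_id_area, sigma_id_perim = sigma_id_perim,
              sigma_eps_area = sigma_eps_area,
              sigma_eps_perim = sigma_eps_perim,
              month_probs = month_probs, n_sharks = n_sharks,
              n_training = n_training,
              second_recapture_prob = second_recapture_prob,
              recapture_prob = recapture_prob,
              max_recaptures = max_recaptures,
              capture_window = capture_window,
              cord_max_age = cord_max_age,
              recapture_lag_range = recapture_lag_range,
              pcl_birth_mean = pcl_birth_mean, pcl_birth_sd = pcl_birth_sd,
              pcl_growth_rate = pcl_growth_rate,
              k0 = k0, k_slope = k_slope, k_sd = k_sd,
              season_start_year = season_start_year, seed = seed)
  validate_config(cfg)
  structure(cfg, class = "synthetic_config")
}

#' @keywords internal
validate_config <- function(cfg) {
  if (abs(sum(cfg$month_probs) - 1) > 1e-12) {
    stop("month_probs must sum to 1 (got ", sum(cfg$month_probs), ")",
         call. = FALSE)
  }
  if (is.null(names(cfg$month_probs)) ||
      !all(names(cfg$month_probs) %in% month.abb)) {
    stop("month_probs must be named with month abbreviations", call. = FALSE)
  }
  sds <- c(cfg$sigma_id_area, cfg$sigma_id_perim,
           cfg$sigma_eps_area, cfg$sigma_eps_perim, cfg$pcl_birth_sd,
           cfg$k_sd)
  if (any(sds < 0)) stop("SDs must be >= 0", call. = FALSE)
  if (cfg$recapture_prob < 0 || cfg$recapture_prob > 1) {
    stop("recapture_prob must be in [0, 1]", call. = FALSE)
  }
  if (cfg$n_sharks < 0 || cfg$n_training < 0) {
    stop("n_sharks and n_training must be >= 0", call. = FALSE)
  }
  if (any(cfg$a1 <= 0, cfg$b1 <= 0)) {
    stop("healing slopes a1 and b1 must be positive", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat(sprintf("  area model  : sqrt(A) = %.3f - %.3f sqrt(t)  (id sd %.3f, eps sd %.3f)\n",
              x$a0, x$a1, x$sigma_id_area, x$sigma_eps_area))
  cat(sprintf("  perim model : P = %.3f - %.3f t  (id sd %.3f, eps sd %.3f)\n",
              x$b0, x$b1, x$sigma_id_perim, x$sigma_eps_perim))
  cat("  birth months:", paste(sprintf("%s %.1f%%", names(x$month_probs),
                                       100 * x$month_probs), collapse = ", "),
      "\n")
  cat(sprintf("  n_sharks %d (+ %d time-zero training), recapture_prob %.3f, capture window %d d\n",
              x$n_sharks, x$n_training, x$recapture_prob, x$capture_window))
  invisible(x)
}

# First day of a named month within the simulated season; months that
# precede the season's first month roll into the following calendar year.
.season_month_starts <- function(month_names, start_year) {
  nums <- match(month_names, month.abb)
  year <- rep(start_year, length(nums))
  if (length(nums) > 1) {
    year <- start_year + cumsum(c(0, diff(nums) < 0))
  }
  as.Date(sprintf("%d-%02d-01", year, nums))
}

#' Simulate a mark-recapture cohort of neonatal sharks
#'
#' Draws birth dates from the configured monthly multinomial (uniform day
#' within month) and gives each shark random intercepts on the two healing
#' scales. Field sharks are captured at a uniform integer age within the
#' capture window and a Bernoulli subset is recaptured after a
#' sampling-night lag; training sharks (`n_training`) are captured at age
#' 0 with cord remnants attached and recaptured at least once — the
#' days-old recaptured neonates from which the regressions can be
#' constructed. Wound measurements are the
#' configured linear trajectories plus individual intercept plus
#' measurement noise, truncated at zero on the linear scale (sqrt-area is
#' then squared). Each measure heals independently: once a shark's
#' noise-free individual trajectory (fixed curve plus its random
#' intercept, no measurement noise) reaches zero on a scale, that measure
#' is recorded as exactly 0 — healing is a state of the animal, not a
#' noisy measurement. The wound is fully closed, `(0, 0)`, once both
#' trajectories have crossed zero; between the area x-intercept (~34.4 d)
#' and the perimeter x-intercept (~35.1 d) a wound has zero area but a
#' small open perimeter.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed; defaults to `config$seed`. The output is fully
#'   reproducible from the seed.
#' @return list of class `synthetic_cohort` with elements
#'   \describe{
#'     \item{events}{capture-event data.frame as from [read_captures()];}
#'     \item{truth}{one row per event: `shark_id`, `date`, `birth_date`,
#'       `true_age` (days), random intercepts `u_area`, `u_perim`, and the
#'       shark's true `closure_age`;}
#'     \item{config}{the configuration used.}
#'   }
#' @export
generate_cohort <- function(config = synthetic_config(), seed = config$seed) {
  validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_sharks + config$n_training
  is_training <- rep(c(FALSE, TRUE), c(config$n_sharks, config$n_training))
  empty_events <- data.frame(
    shark_id = character(0), date = as.Date(character(0)),
    wound_area = numeric(0), wound_perimeter = numeric(0),
    pcl = numeric(0), mass = numeric(0), site = character(0),
    sex = character(0), cord_remnants = logical(0),
    stringsAsFactors = FALSE)
  if (n == 0) {
    return(structure(list(events = empty_events,
                          truth = cbind(empty_events[, 1:2, drop = FALSE],
                                        birth_date = as.Date(character(0)),
                                        true_age = numeric(0),
                                        training = logical(0),
                                        u_area = numeric(0),
                                        u_perim = numeric(0),
                                        closure_age = numeric(0)),
                          config = config),
                     class = "synthetic_cohort"))
  }
  ids <- sprintf("S%04d", seq_len(n))

  # births: month from the multinomial, day uniform within that month
  mstarts <- .season_month_starts(names(config$month_probs),
                                  config$season_start_year)
  mlen <- vapply(mstarts, function(d) {
    as.integer(seq(d, by = "1 month", length.out = 2)[2] - d)
  }, integer(1))
  midx <- sample.int(length(mstarts), n, replace = TRUE,
                     prob = config$month_probs)
  bday <- vapply(seq_len(n), function(i) sample.int(mlen[midx[i]], 1),
                 integer(1))
  birth <- mstarts[midx] + (bday - 1L)

  # individual random intercepts and per-shark closure age
  u <- rnorm(n, 0, config$sigma_id_area)
  v <- rnorm(n, 0, config$sigma_id_perim)
  closure_area <- ifelse(config$a0 + u <= 0, 0,
                         ((config$a0 + u) / config$a1)^2)
  closure_perim <- pmax(0, (config$b0 + v) / config$b1)
  # the wound is fully closed once BOTH measures have reached zero; between
  # the two x-intercepts the area is healed while the perimeter is still open
  closure <- pmax(closure_area, closure_perim)

  # capture ages: field sharks first-captured uniformly in the window with
  # Bernoulli recaptures; training sharks captured at age 0 and recaptured
  # once, twice with probability second_recapture_prob
  age1 <- ifelse(is_training, 0L,
                 sample.int(config$capture_window + 1L, n,
                            replace = TRUE) - 1L)
  lagr <- config$recapture_lag_range
  ages <- vector("list", n)
  for (i in seq_len(n)) {
    a <- age1[i]
    if (is_training[i]) {
      a <- c(a, a + sample(seq(lagr[1], lagr[2]), 1))
      if (rbinom(1, 1, config$second_recapture_prob) == 1L) {
        a <- c(a, a[2] + sample(seq(lagr[1], lagr[2]), 1))
      }
    } else {
      k <- 0L
      while (k < config$max_recaptures &&
             rbinom(1, 1, config$recapture_prob) == 1L) {
        a <- c(a, a[length(a)] + sample(seq(lagr[1], lagr[2]), 1))
        k <- k + 1L
      }
    }
    ages[[i]] <- a
  }
  n_ev <- lengths(ages)
  idx <- rep(seq_len(n), n_ev)
  age <- unlist(ages)

  # wound measurements on the linear scales, truncated at zero
  s_free <- config$a0 - config$a1 * sqrt(age) + u[idx]   # noise-free sqrt-area
  p_free <- config$b0 - config$b1 * age + v[idx]         # noise-free perimeter
  closed <- s_free <= 0 & p_free <= 0
  s_obs <- pmax(0, s_free + rnorm(length(age), 0, config$sigma_eps_area))
  p_obs <- pmax(0, p_free + rnorm(length(age), 0, config$sigma_eps_perim))
  # a measure whose noise-free trajectory has reached zero is healed: it is
  # recorded as exactly 0 (a state), not as a noisy measurement
  area <- ifelse(s_free <= 0, 0, s_obs^2)
  perim <- ifelse(p_free <= 0, 0, p_obs)

  # morphometrics: linear early growth; condition declines with age
  pcl0 <- rnorm(n, config$pcl_birth_mean, config$pcl_birth_sd)
  pcl <- round(pcl0[idx] + config$pcl_growth_rate * age, 1)
  k <- pmax(0.3, config$k0 + config$k_slope * age +
                   rnorm(length(age), 0, config$k_sd))
  mass <- round(k * pcl^3 / 1e5, 3)

  site <- sample(.site_pool, n, replace = TRUE)
  sex <- sample(c("M", "F"), n, replace = TRUE)

  events <- data.frame(
    shark_id = ids[idx],
    date = birth[idx] + age,
    wound_area = area,
    wound_perimeter = perim,
    pcl = pcl,
    mass = mass,
    site = site[idx],
    sex = sex[idx],
    cord_remnants = age <= config$cord_max_age & !closed,
    stringsAsFactors = FALSE
  )
  ord <- order(events$shark_id, events$date)
  truth <- data.frame(
    shark_id = ids[idx],
    date = birth[idx] + age,
    birth_date = birth[idx],
    true_age = as.numeric(age),
    training = is_training[idx],
    u_area = u[idx],
    u_perim = v[idx],
    closure_age = closure[idx],
    stringsAsFactors = FALSE
  )
  events <- events[ord, , drop = FALSE]
  truth <- truth[ord, , drop = FALSE]
  rownames(events) <- rownames(truth) <- NULL
  structure(list(events = events, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n_id <- length(unique(x$events$shark_id))
  cat("<synthetic_cohort> ", n_id, " sharks, ", nrow(x$events),
      " capture events\n", sep = "")
  invisible(x)
}

#' Time-at-liberty validation reference table
#'
#' The published validation set: 17 recaptured neonates with initial and
#' recapture dates, actual time at liberty (TAL), wound-predicted time at
#' liberty (pTAL) and their absolute difference. The underlying wound
#' measurements were not published, so `ptal` here is reference data, not
#' recomputable. One row (shark 3) prints a TAL inconsistent with its two
#' dates — a typo in the source, stored as printed.
#'
#' @return data.frame with columns `shark`, `initial_date`,
#'   `recapture_date` (`Date`), `tal`, `ptal`, `abs_diff` (days).
#' @export
validation_reference <- function() {
  path <- system.file("extdata", "validation_reference.csv",
                      package = "uwcager", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  data.frame(
    shark = as.integer(raw$shark),
    initial_date = parse_capture_date(raw$initial_date),
    recapture_date = parse_capture_date(raw$recapture_date),
    tal = as.integer(raw$tal),
    ptal = as.integer(raw$ptal),
    abs_diff = as.integer(raw$abs_diff),
    stringsAsFactors = FALSE
  )
}
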