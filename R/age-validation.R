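#' Estimate relative age from wound size
#'
#' Inverts the two fitted healing curves. From area:
#' `age = ((a0 - sqrt(area)) / a1)^2`, valid only on the physical branch
#' `sqrt(area) <= a0` — naively squaring `(sqrt(area) - a0)/a1` would turn
#' a wound larger than the age-0 intercept into a positive "ghost" age, so
#' such wounds are clamped to age 0. From perimeter:
#' `age = (b0 - perimeter) / b1`, clamped at 0. The combined estimate is
#' the unweighted mean of the two (no variance components are available to
#' weight them). A zero measurement is a healed state, not a size: it only
#' bounds age from below by that curve's x-intercept. An event with either
#' measure at zero is therefore censored and both components are left
#' undefined — inverting the non-zero measure alone would silently change
#' the estimator from a two-curve mean to a single curve.
#'
#' @param events capture-event data.frame (or any data.frame with
#'   `wound_area` and `wound_perimeter` columns).
#' @param fit a `wound_model_fit`.
#' @return data.frame with `age_from_area`, `age_from_perimeter`,
#'   `age_combined` (days; `NA` when censored or a field is missing) and
#'   logical `censored` (wound healed on at least one measure).
#' @export
estimate_age <- function(events, fit) {
  a <- events$wound_area
  p <- events$wound_perimeter
  n <- length(a)
  censored <- !is.na(a) & !is.na(p) & (a == 0 | p == 0)
  s <- sqrt(a)
  age_a <- ifelse(s >= fit$a0, 0, ((fit$a0 - s) / fit$a1)^2)
  age_p <- pmax(0, (fit$b0 - p) / fit$b1)
  age_a[censored | is.na(a)] <- NA_real_
  age_p[censored | is.na(p)] <- NA_real_
  combined <- ifelse(is.na(age_a) | is.na(age_p), NA_real_,
                     (age_a + age_p) / 2)
  data.frame(age_from_area = age_a, age_from_perimeter = age_p,
             age_combined = combined, censored = censored)
}

#' Predicted vs actual time at liberty for one recaptured shark
#'
#' The actual time at liberty (TAL) is the elapsed days between initial
#' capture and recapture; the predicted TAL (pTAL) is the difference of
#' the combined age estimates at the two events. Sharks with a closed
#' umbilicus at either event, or that were used to construct the
#' regressions, are excluded with a reason rather than scored. Histories
#' with more than two events use the first and last capture.
#'
#' @param history one shark's date-ordered capture events (>= 2 rows).
#' @param fit a `wound_model_fit`.
#' @param training_ids shark ids used to fit the regressions (excluded).
#' @return list with `status = "ok"` and a `record` (fields `shark_id`,
#'   `initial_date`, `recapture_date`, `tal`, `ptal`, `abs_diff`), or
#'   `status = "excluded"` and a `reason`.
#' @export
predict_tal <- function(history, fit, training_ids = character(0)) {
  if (nrow(history) < 2) {
    stop("predict_tal requires a history with >= 2 events", call. = FALSE)
  }
  id <- history$shark_id[1]
  if (id %in% training_ids) {
    return(list(status = "excluded", shark_id = id,
                reason = "used to construct the regression relationships"))
  }
  ev <- history[c(1, nrow(history)), , drop = FALSE]
  est <- estimate_age(ev, fit)
  if (any(est$censored)) {
    return(list(status = "excluded", shark_id = id,
                reason = "closed umbilicus at initial capture and/or recapture"))
  }
  if (any(is.na(est$age_combined))) {
    return(list(status = "excluded", shark_id = id,
                reason = "missing wound measurement"))
  }
  tal <- elapsed_days(ev$date[1], ev$date[2])
  ptal <- est$age_combined[2] - est$age_combined[1]
  list(status = "ok",
       record = data.frame(shark_id = id,
                           initial_date = ev$date[1],
                           recapture_date = ev$date[2],
                           tal = tal, ptal = ptal,
                           abs_diff = abs(tal - ptal),
                           stringsAsFactors = FALSE))
}

#' Validate a fitted scheme on all recaptured sharks
#'
#' Applies [predict_tal()] to every history with at least two events.
#'
#' @param histories a `shark_histories` list.
#' @param fit a `wound_model_fit`.
#' @param training_ids shark ids in the regression training set.
#' @return list with `records` (data.frame of validation records) and
#'   `exclusions` (data.frame of `shark_id`, `reason`).
#' @export
validate_cohort <- function(histories, fit, training_ids = character(0)) {
  records <- list()
  excl <- list()
  for (h in histories) {
    if (nrow(h) < 2) next
    res <- predict_tal(h, fit, training_ids)
    if (res$status == "ok") {
      records[[length(records) + 1L]] <- res$record
    } else {
      excl[[length(excl) + 1L]] <- data.frame(
        shark_id = res$shark_id, reason = res$reason,
        stringsAsFactors = FALSE)
    }
  }
  empty_rec <- data.frame(shark_id = character(0),
                          initial_date = as.Date(character(0)),
                          recapture_date = as.Date(character(0)),
                          tal = integer(0), ptal = numeric(0),
                          abs_diff = numeric(0), stringsAsFactors = FALSE)
  list(records = if (length(records)) do.call(rbind, records) else empty_rec,
       exclusions = if (length(excl)) do.call(rbind, excl) else
         data.frame(shark_id = character(0), reason = character(0),
                    stringsAsFactors = FALSE))
}

#' Summarise validation error
#'
#' Mean and sample standard deviation (n - 1 denominator) of the absolute
#' TAL - pTAL differences, raw and rounded to whole days.
#'
#' @param records validation records (need a column `abs_diff`), or a
#'   numeric vector of absolute differences.
#' @return list with `mean_abs_diff`, `sd_abs_diff`, `n`, and rounded
#'   `mean_days`, `sd_days`.
#' @export
summarize_validation <- function(records) {
  d <- if (is.data.frame(records)) records$abs_diff else as.numeric(records)
  n <- length(d)
  if (n < 2) stop("need at least 2 validation records for a SD", call. = FALSE)
  list(mean_abs_diff = mean(d), sd_abs_diff = sd(d), n = n,
       mean_days = round(mean(d)), sd_days = round(sd(d)))
}
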