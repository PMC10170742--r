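#' Midpoint age of a neonatal wound class
#'
#' The age assigned to a shark classified at first capture: the midpoint
#' `(t_min + t_max) / 2` of its class interval — 6, 18 and 30 days for
#' UWC1-3 under the default 12/24/36-day boundaries. Juveniles (UWC4)
#' have no upper age bound and are not assigned an age.
#'
#' @param uwc integer class label(s) in 1-3.
#' @param scheme a `uwc_scheme`.
#' @return midpoint age(s) in days.
#' @export
midpoint_age <- function(uwc, scheme) {
  if (any(is.na(uwc)) || any(!uwc %in% 1:3)) {
    stop("midpoint age is defined for UWC1-3 only; sharks with a closed ",
         "umbilicus (UWC4, juveniles) are not considered", call. = FALSE)
  }
  lo <- c(0, scheme$boundaries[1], scheme$boundaries[2])
  hi <- scheme$boundaries
  (lo[uwc] + hi[uwc]) / 2
}

#' Back-calculate parturition dates from classified captures
#'
#' For each shark's FIRST capture with an open-wound class (UWC1-3), the
#' estimated date of parturition is the capture date minus the midpoint
#' age of its class (rounded to whole days for calendar arithmetic).
#' Dates are absolute, so a January capture back-calculates into December
#' of the previous year. Juveniles (UWC4) and unclassifiable events are
#' skipped and counted.
#'
#' @param labeled classified events from [classify_cohort()].
#' @param scheme the `uwc_scheme` used for the labels.
#' @return data.frame with `shark_id`, `capture_date`, `uwc`, `t0`
#'   (parturition `Date`) and `month` (integer 1-12); attributes
#'   `n_skipped_uwc4` and `n_skipped_unclassifiable`.
#' @export
backcalculate <- function(labeled, scheme) {
  if (nrow(labeled) == 0) {
    out <- data.frame(shark_id = character(0),
                      capture_date = as.Date(character(0)),
                      uwc = integer(0), t0 = as.Date(character(0)),
                      month = integer(0), stringsAsFactors = FALSE)
    attr(out, "n_skipped_uwc4") <- 0L
    attr(out, "n_skipped_unclassifiable") <- 0L
    return(out)
  }
  first_idx <- tapply(seq_len(nrow(labeled)), labeled$shark_id,
                      function(i) i[which.min(labeled$date[i])])
  first <- labeled[unlist(first_idx), , drop = FALSE]
  n_uwc4 <- sum(first$uwc == 4L, na.rm = TRUE)
  n_na <- sum(is.na(first$uwc))
  neo <- first[!is.na(first$uwc) & first$uwc %in% 1:3, , drop = FALSE]
  mid <- if (nrow(neo)) round(midpoint_age(neo$uwc, scheme)) else numeric(0)
  t0 <- neo$date - mid
  out <- data.frame(shark_id = neo$shark_id, capture_date = neo$date,
                    uwc = neo$uwc, t0 = t0,
                    month = as.integer(format(t0, "%m")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out <- out[order(out$shark_id), , drop = FALSE]
  attr(out, "n_skipped_uwc4") <- n_uwc4
  attr(out, "n_skipped_unclassifiable") <- n_na
  out
}

#' Monthly distribution of back-calculated parturitions
#'
#' @param estimates output of [backcalculate()] (or any data.frame with an
#'   integer `month` column).
#' @return data.frame with `month` (integer), `month_name`, `count` and
#'   `pct` (percentages summing to 100 up to rounding), one row per month
#'   observed, in season order (first appearance of each month by date
#'   when `t0` is present, else calendar order).
#' @export
month_distribution <- function(estimates) {
  if (nrow(estimates) == 0) {
    return(data.frame(month = integer(0), month_name = character(0),
                      count = integer(0), pct = numeric(0)))
  }
  if (!is.null(estimates$t0)) {
    ord_months <- unique(as.integer(format(sort(estimates$t0), "%m")))
  } else {
    ord_months <- sort(unique(estimates$month))
  }
  count <- vapply(ord_months, function(m) sum(estimates$month == m),
                  integer(1))
  data.frame(month = ord_months, month_name = month.abb[ord_months],
             count = count, pct = 100 * count / sum(count))
}

#' Pearson chi-square test of birth-month seasonality
#'
#' Tests the observed monthly parturition counts against a uniform
#' expectation over the months included in the season window:
#' `X^2 = sum((O - E)^2 / E)` with `months - 1` degrees of freedom.
#'
#' @param counts named or unnamed vector of per-month counts (only the
#'   months in the season window).
#' @return list with `statistic`, `df` and `p_value`.
#' @export
seasonality_test <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2) {
    stop("need counts for at least 2 months", call. = FALSE)
  }
  if (sum(counts) == 0) {
    stop("all expected counts are zero", call. = FALSE)
  }
  ht <- suppressWarnings(chisq.test(counts))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}
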