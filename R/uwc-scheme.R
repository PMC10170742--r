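#' Derive an umbilical wound classification scheme from a fit
#'
#' Evaluates the fitted healing curves at the class boundary ages to get
#' the critical wound sizes that separate the classes: the area curve at
#' the first boundary (12 d by default) and the perimeter line at the
#' second (24 d). Rounded values (3 d.p. for area, 2 d.p. for perimeter)
#' are what reports print; classification always compares against the
#' unrounded values.
#'
#' @param fit a `wound_model_fit`.
#' @param boundaries strictly increasing ages (days) splitting the
#'   neonatal period into three equal-width classes; the last boundary
#'   must not exceed the closure day.
#' @return object of class `uwc_scheme`: `boundaries`, `crit_area`,
#'   `crit_perimeter` (unrounded), `crit_area_report`,
#'   `crit_perimeter_report` (rounded), `closure`, and the source `fit`.
#' @examples
#' sch <- derive_scheme(wound_model_fit(0.311, 0.053, 1.299, 0.037))
#' sch$crit_area_report       # 0.016 cm^2
#' sch$crit_perimeter_report  # 0.41 cm
#' @export
derive_scheme <- function(fit, boundaries = c(12, 24, 36)) {
  if (length(boundaries) != 3 || any(diff(boundaries) <= 0)) {
    stop("boundaries must be three strictly increasing ages", call. = FALSE)
  }
  cl <- closure_age(fit)
  if (boundaries[1] < 0 || boundaries[3] > cl$day) {
    stop("boundaries must lie within (0, ", cl$day,
         "] (the closure day for this fit)", call. = FALSE)
  }
  crit_area <- (fit$a0 - fit$a1 * sqrt(boundaries[1]))^2
  crit_perimeter <- fit$b0 - fit$b1 * boundaries[2]
  if (crit_area <= 0 || crit_perimeter <= 0) {
    stop("critical values must be positive; boundaries too close to closure",
         call. = FALSE)
  }
  structure(list(
    boundaries = boundaries,
    crit_area = crit_area,
    crit_perimeter = crit_perimeter,
    crit_area_report = round(crit_area, 3),
    crit_perimeter_report = round(crit_perimeter, 2),
    closure = cl,
    fit = fit
  ), class = "uwc_scheme")
}

#' @export
print.uwc_scheme <- function(x, ...) {
  b <- x$boundaries
  cat("<uwc_scheme>\n")
  cat(sprintf("  UWC1: age [0, %g) d    area > %.3f cm^2, perimeter > %.2f cm\n",
              b[1], x$crit_area_report, x$crit_perimeter_report))
  cat(sprintf("  UWC2: age [%g, %g) d   area <= %.3f cm^2, perimeter > %.2f cm\n",
              b[1], b[2], x$crit_area_report, x$crit_perimeter_report))
  cat(sprintf("  UWC3: age [%g, %g) d  perimeter <= %.2f cm\n",
              b[2], b[3], x$crit_perimeter_report))
  cat(sprintf("  UWC4: age >= %g d      wound closed (0, 0)\n", b[3]))
  cat(sprintf("  closure at %.2f d (day %d)\n", x$closure$days, x$closure$day))
  invisible(x)
}

#' Classify wound sizes into umbilical wound classes
#'
#' Decision rule, in order of precedence: a fully closed wound (area and
#' perimeter both zero) is UWC4 (juvenile); otherwise perimeter at or
#' below its critical value assigns UWC3 — perimeter must decide first,
#' because wound area overlaps between UWC2 and UWC3 and cannot separate
#' them; otherwise area above its critical value assigns UWC1, and the
#' remainder (area at or below critical, ties included) is UWC2. The
#' combination "area above critical but perimeter at or below critical"
#' is not covered by the published class table; it is still assigned
#' (UWC3, by the precedence rule) but flagged as inconsistent.
#'
#' @param area,perimeter numeric vectors (recycled) of wound sizes; `NA`
#'   gives an `NA` (unclassifiable) label.
#' @param scheme a `uwc_scheme`.
#' @return data.frame with integer `uwc` (1-4 or `NA`) and logical
#'   `consistent`.
#' @export
classify_wound <- function(area, perimeter, scheme) {
  n <- max(length(area), length(perimeter))
  area <- rep_len(area, n)
  perimeter <- rep_len(perimeter, n)
  if (any(area < 0 | perimeter < 0, na.rm = TRUE)) {
    stop("wound sizes must be non-negative", call. = FALSE)
  }
  uwc <- rep(NA_integer_, n)
  consistent <- rep(NA, n)
  ok <- !is.na(area) & !is.na(perimeter)
  a <- area[ok]; p <- perimeter[ok]
  lab <- ifelse(a == 0 & p == 0, 4L,
                ifelse(p <= scheme$crit_perimeter, 3L,
                       ifelse(a > scheme$crit_area, 1L, 2L)))
  uwc[ok] <- lab
  consistent[ok] <- !(a > scheme$crit_area & p <= scheme$crit_perimeter &
                        !(a == 0 & p == 0))
  data.frame(uwc = uwc, consistent = consistent)
}

#' Classify a capture event
#'
#' @param event one-row capture-event data.frame.
#' @param scheme a `uwc_scheme`.
#' @return list with `uwc` (integer 1-4, or `NA` when a wound field is
#'   missing) and `consistent`.
#' @export
classify <- function(event, scheme) {
  res <- classify_wound(event$wound_area[1], event$wound_perimeter[1], scheme)
  list(uwc = res$uwc, consistent = res$consistent)
}

#' Classify every event in a cohort
#'
#' @param events capture-event data.frame.
#' @param scheme a `uwc_scheme`.
#' @return `events` with added columns `uwc` and `uwc_consistent`;
#'   attribute `counts` holds the per-class tally (named "1".."4") plus
#'   `"unclassifiable"` for events with missing wound fields.
#' @export
classify_cohort <- function(events, scheme) {
  res <- classify_wound(events$wound_area, events$wound_perimeter, scheme)
  events$uwc <- res$uwc
  events$uwc_consistent <- res$consistent
  counts <- vapply(1:4, function(k) sum(res$uwc == k, na.rm = TRUE),
                   integer(1))
  names(counts) <- as.character(1:4)
  attr(events, "counts") <- c(counts, unclassifiable = sum(is.na(res$uwc)))
  events
}

#' Per-class counts of a labelled cohort
#'
#' @param labeled output of [classify_cohort()].
#' @return named integer vector over classes 1-4.
#' @export
uwc_counts <- function(labeled) {
  vapply(as.character(1:4),
         function(k) sum(labeled$uwc == as.integer(k), na.rm = TRUE),
         integer(1))
}
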