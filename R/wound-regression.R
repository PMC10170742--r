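#' Assemble training pairs from days-old recaptured neonates
#'
#' Only histories whose FIRST capture carries umbilical-cord remnants
#' qualify: cord remnants are shed within the first couple of days of
#' life, so such an animal has a known ("time zero") age anchor. The
#' anchor event is assigned age 0 and later events get the elapsed days
#' from it. Anchored sharks that were never recaptured are skipped —
#' a single time-zero point carries no information about the healing
#' rate, and only subsequently recaptured days-old neonates enter the
#' regression. Events with a closed wound (area and perimeter both zero)
#' carry no information about the linear healing trajectories — the
#' truncation at zero would bias the fit — so they are excluded from the
#' response but counted in the `n_closed_excluded` attribute.
#'
#' @param histories a `shark_histories` list from [build_histories()].
#' @return data.frame with columns `shark_id`, `age` (days), `area`
#'   (cm^2), `perimeter` (cm); attributes `anchor_ids` (the shark ids
#'   used, i.e. the regression training set) and `n_closed_excluded`.
#' @export
assemble_training_pairs <- function(histories) {
  rows <- list()
  anchor_ids <- character(0)
  n_closed <- 0L
  for (h in histories) {
    cr <- h$cord_remnants
    anchored_first <- isTRUE(cr[1])
    late_anchor <- any(vapply(seq_len(nrow(h))[-1],
                              function(i) isTRUE(cr[i]), logical(1)))
    if (!anchored_first && late_anchor) {
      stop("cord remnants recorded on a non-first capture for shark ",
           h$shark_id[1], " (inconsistent aging anchor)", call. = FALSE)
    }
    if (!anchored_first || nrow(h) < 2) next
    anchor_ids <- c(anchor_ids, h$shark_id[1])
    age <- elapsed_days(h$date[1], h$date)
    open <- !is.na(h$wound_area) & !is.na(h$wound_perimeter) &
      (h$wound_area > 0 | h$wound_perimeter > 0)
    n_closed <- n_closed + sum(!is.na(h$wound_area) &
                                 !is.na(h$wound_perimeter) & !open)
    keep <- open
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      shark_id = h$shark_id[keep], age = age[keep],
      area = h$wound_area[keep], perimeter = h$wound_perimeter[keep],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(shark_id = character(0), age = numeric(0),
               area = numeric(0), perimeter = numeric(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "anchor_ids") <- anchor_ids
  attr(out, "n_closed_excluded") <- n_closed
  out
}

# Fit response ~ predictor with a per-shark random intercept by REML;
# fall back to OLS when the intercept variance degenerates to zero (or
# the mixed fit fails outright, e.g. on noise-free data).
.fit_one <- function(response, predictor, id) {
  df <- data.frame(y = response, x = predictor, id = factor(id))
  mixed <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(y ~ x + (1 | id), data = df, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    )),
    error = function(e) NULL)
  if (!is.null(mixed) && !lme4::isSingular(mixed, tol = 1e-6)) {
    vc <- as.data.frame(lme4::VarCorr(mixed))
    fe <- lme4::fixef(mixed)
    return(list(intercept = unname(fe[1]), slope = unname(fe[2]),
                var_id = vc$vcov[vc$grp == "id"],
                var_eps = vc$vcov[vc$grp == "Residual"],
                method = "REML"))
  }
  ols <- stats::lm(y ~ x, data = df)
  list(intercept = unname(coef(ols)[1]), slope = unname(coef(ols)[2]),
       var_id = 0,
       var_eps = mean(stats::residuals(ols)^2),
       method = "OLS")
}

#' Fit the two umbilical healing regressions
#'
#' Area model: `sqrt(area) = a0 - a1 * sqrt(age)` (the back-transformed
#' curve is the quadratic decline `area = (a0 - a1 sqrt(age))^2`).
#' Perimeter model: `perimeter = b0 - b1 * age`. Both are linear
#' mixed-effects models with a per-shark random intercept (repeated
#' measures of recaptured individuals), estimated by restricted maximum
#' likelihood. Random slopes are not identifiable from at most three
#' points per shark and are not attempted. When the random-intercept
#' variance estimate degenerates to zero the fit falls back to ordinary
#' least squares; the method used is recorded in the fit.
#'
#' @param pairs training pairs from [assemble_training_pairs()].
#' @return object of class `wound_model_fit`: coefficients `a0`, `a1`,
#'   `b0`, `b1` (slopes stored positive, as decline rates), variance
#'   components `var_id_area`, `var_eps_area`, `var_id_perim`,
#'   `var_eps_perim`, `n_individuals`, `n_observations`, fitting methods,
#'   and a `nonshrinking` flag raised when an estimated slope is not
#'   positive.
#' @seealso [closure_age()], [derive_scheme()], [estimate_age()]
#' @export
fit_wound_models <- function(pairs) {
  pairs <- pairs[complete.cases(pairs[, c("shark_id", "age", "area",
                                          "perimeter")]), , drop = FALSE]
  # a zero measurement is a healed (or floor-truncated) state, not a size
  # on the linear trajectory: each response keeps only its positive rows
  pa <- pairs[pairs$area > 0, , drop = FALSE]
  pp <- pairs[pairs$perimeter > 0, , drop = FALSE]
  for (sub in list(area = pa, perimeter = pp)) {
    n_id <- length(unique(sub$shark_id))
    if (n_id < 2 || nrow(sub) < 4 || length(unique(sub$age)) < 2) {
      stop("insufficient training data: need >= 2 individuals, >= 4 ",
           "observations and >= 2 distinct ages per response (got ", n_id,
           " / ", nrow(sub), " / ", length(unique(sub$age)), ")",
           call. = FALSE)
    }
  }
  n_id <- length(unique(pairs$shark_id))
  fa <- .fit_one(sqrt(pa$area), sqrt(pa$age), pa$shark_id)
  fp <- .fit_one(pp$perimeter, pp$age, pp$shark_id)
  fit <- structure(list(
    a0 = fa$intercept, a1 = -fa$slope,
    b0 = fp$intercept, b1 = -fp$slope,
    var_id_area = fa$var_id, var_eps_area = fa$var_eps,
    var_id_perim = fp$var_id, var_eps_perim = fp$var_eps,
    n_individuals = n_id, n_observations = nrow(pairs),
    method_area = fa$method, method_perim = fp$method,
    nonshrinking = (-fa$slope <= 0) || (-fp$slope <= 0)
  ), class = "wound_model_fit")
  if (fit$nonshrinking) {
    warning("fitted wound-size slope is not positive: wounds do not ",
            "shrink under this fit", call. = FALSE)
  }
  fit
}

#' Construct a wound-model fit from known coefficients
#'
#' Mainly for applying a published set of healing-curve coefficients
#' without refitting (e.g. curves reported for another population).
#'
#' @param a0,a1,b0,b1 curve coefficients (slopes as positive decline
#'   rates).
#' @return `wound_model_fit` object with zero variance components.
#' @export
wound_model_fit <- function(a0, a1, b0, b1) {
  if (a1 <= 0 || b1 <= 0) {
    stop("decline rates a1 and b1 must be positive", call. = FALSE)
  }
  structure(list(a0 = a0, a1 = a1, b0 = b0, b1 = b1,
                 var_id_area = 0, var_eps_area = 0,
                 var_id_perim = 0, var_eps_perim = 0,
                 n_individuals = 0L, n_observations = 0L,
                 method_area = "fixed", method_perim = "fixed",
                 nonshrinking = FALSE),
            class = "wound_model_fit")
}

#' @export
print.wound_model_fit <- function(x, ...) {
  cat("<wound_model_fit>\n")
  cat(sprintf("  sqrt(area) = %.4f - %.4f sqrt(age)   [%s]\n",
              x$a0, x$a1, x$method_area))
  cat(sprintf("  perimeter  = %.4f - %.4f age         [%s]\n",
              x$b0, x$b1, x$method_perim))
  cat(sprintf("  variance components: id (%.2e, %.2e), residual (%.2e, %.2e)\n",
              x$var_id_area, x$var_id_perim, x$var_eps_area, x$var_eps_perim))
  cat(sprintf("  %d observations on %d individuals\n",
              x$n_observations, x$n_individuals))
  if (isTRUE(x$nonshrinking)) cat("  WARNING: non-shrinking fit\n")
  invisible(x)
}

#' Wound-closure age from a fitted model
#'
#' The x-intercepts of the two healing curves give the age at which each
#' measure reaches zero; complete closure is the later of the two, and
#' its integer ceiling is the closure day that bounds the neonatal
#' period (36 days under the default coefficients: area intercept
#' `(a0/a1)^2` = 34.43 d, perimeter intercept `b0/b1` = 35.11 d).
#'
#' @param fit a `wound_model_fit`.
#' @return list with `area_days`, `perimeter_days` (the two x-intercepts),
#'   `days` (their maximum) and `day` (integer ceiling).
#' @export
closure_age <- function(fit) {
  if (fit$a1 <= 0 || fit$b1 <= 0) {
    stop("closure age requires positive decline rates", call. = FALSE)
  }
  area_days <- (max(0, fit$a0) / fit$a1)^2
  perim_days <- max(0, fit$b0) / fit$b1
  days <- max(area_days, perim_days)
  list(area_days = area_days, perimeter_days = perim_days,
       days = days, day = as.integer(ceiling(days)))
}
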