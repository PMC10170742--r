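#' Fulton's body condition factor
#'
#' `K = 1e5 * M / PCL^3` with mass `M` in kg and precaudal length in cm;
#' the 1e5 factor scales K to order 1 for neonatal sharks.
#'
#' @param mass body mass (kg), > 0.
#' @param pcl precaudal length (cm), > 0.
#' @return K (dimensionless on the 1e5 kg cm^-3 scale). Vectorised.
#' @examples
#' fulton_k(1.0, 100)     # 0.1
#' fulton_k(0.995, 41.7)  # ~1.37, a typical neonate
#' @export
fulton_k <- function(mass, pcl) {
  if (any(!is.na(mass) & mass <= 0) || any(!is.na(pcl) & pcl <= 0)) {
    stop("mass and pcl must be positive", call. = FALSE)
  }
  1e5 * mass / pcl^3
}

#' Build condition records from a labelled cohort
#'
#' One record per classified event with non-missing morphometrics;
#' events missing mass or PCL are dropped (no imputation) and counted in
#' the `n_dropped_missing` attribute.
#'
#' @param labeled classified events from [classify_cohort()].
#' @return data.frame with `shark_id`, `uwc`, `pcl`, `mass`, `k`.
#' @export
condition_records <- function(labeled) {
  ok <- !is.na(labeled$uwc) & !is.na(labeled$pcl) & !is.na(labeled$mass)
  out <- data.frame(shark_id = labeled$shark_id[ok],
                    uwc = labeled$uwc[ok],
                    pcl = labeled$pcl[ok],
                    mass = labeled$mass[ok],
                    stringsAsFactors = FALSE)
  out$k <- fulton_k(out$mass, out$pcl)
  attr(out, "n_dropped_missing") <- sum(!ok)
  out
}

#' Compare a morphometric response across wound classes
#'
#' Screens each class for normality with the Shapiro-Wilk test (reject
#' flag at W < 0.90; the screen is reported but does not gate the ANOVA),
#' then runs a one-way ANOVA of the response on class and, for pairwise
#' contrasts, Tukey's honest significant difference test at family-wise
#' alpha 0.05. Classes with fewer than 2 records are excluded with a
#' warning.
#'
#' @param records condition records from [condition_records()].
#' @param response one of `"pcl"`, `"mass"`, `"k"`.
#' @param w_critical Shapiro-Wilk W below which normality is rejected.
#' @return list with `shapiro` (per-class W and reject flag), `anova`
#'   (`f`, `df1`, `df2`, `p_value`), `tukey` (data.frame of pairwise
#'   differences and adjusted p), `group_means`, and `excluded_groups`.
#' @export
compare_groups <- function(records, response = c("pcl", "mass", "k"),
                           w_critical = 0.90) {
  response <- match.arg(response)
  y <- records[[response]]
  g <- records$uwc
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- g[keep]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("excluding class(es) with < 2 records: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep2 <- !(as.character(g) %in% small)
    y <- y[keep2]; g <- g[keep2]
  }
  groups <- sort(unique(g))
  if (length(groups) < 2) {
    stop("need >= 2 classes with >= 2 records each", call. = FALSE)
  }
  shapiro <- do.call(rbind, lapply(groups, function(k) {
    yk <- y[g == k]
    w <- if (length(yk) >= 3 && length(yk) <= 5000 && stats::var(yk) > 0) {
      unname(shapiro.test(yk)$statistic)
    } else NA_real_
    data.frame(uwc = k, n = length(yk), w = w,
               reject_normality = !is.na(w) & w < w_critical)
  }))
  gf <- factor(g)
  fit <- aov(y ~ gf)
  an <- summary(fit)[[1]]
  anova_res <- list(f = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
                    p_value = an$`Pr(>F)`[1])
  tk <- TukeyHSD(fit, conf.level = 0.95)$gf
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  tukey <- data.frame(group1 = pairs[, 2], group2 = pairs[, 1],
                      diff = tk[, "diff"], lwr = tk[, "lwr"],
                      upr = tk[, "upr"], p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < 0.05,
                      stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  means <- vapply(groups, function(k) mean(y[g == k]), numeric(1))
  names(means) <- as.character(groups)
  list(response = response, shapiro = shapiro, anova = anova_res,
       tukey = tukey, group_means = means,
       excluded_groups = as.integer(small))
}
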