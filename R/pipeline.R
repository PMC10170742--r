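# Minimal structural validation of the pipeline summary against the
# shipped JSON schema (required keys and basic types only).
check_summary <- function(summary,
                          schema_path = system.file("schema",
                                                    "summary_schema.json",
                                                    package = "uwcager",
                                                    mustWork = TRUE)) {
  schema <- jsonlite::read_json(schema_path)
  missing <- setdiff(unlist(schema$required), names(summary))
  if (length(missing) > 0) {
    stop("summary is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (fld in c("coefficients", "critical_values", "validation")) {
    sub <- schema$properties[[fld]]
    miss <- setdiff(unlist(sub$required), names(summary[[fld]]))
    if (length(miss) > 0) {
      stop("summary$", fld, " is missing field(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full wound-classification pipeline
#'
#' Executes, in order: read (or accept) the capture table, group into
#' histories, assemble the days-old training set, fit the two healing
#' regressions, derive the classification scheme, classify every event,
#' estimate per-event ages, validate by predicted vs actual time at
#' liberty (training sharks excluded), back-calculate parturition dates
#' and their monthly distribution with a seasonality chi-square, and
#' compare morphometrics (PCL, mass, Fulton's K) across classes. Each
#' stage logs how many records it used and excluded — every stage has an
#' exclusion rule, and silent exclusions are how such analyses go wrong.
#'
#' @param input capture CSV path, or a capture-event data.frame.
#' @param out_dir output directory (created if needed); when `NULL`,
#'   nothing is written and the bundle is only returned.
#' @param boundaries class-boundary ages in days; `NULL` (default) splits
#'   the fitted closure day into three equal intervals, the construction
#'   the published 12/24/36-day scheme follows when closure is at 36 days.
#' @param season_months integer months of the parturition season window,
#'   in season order.
#' @param date_format date dialect for CSV input/output.
#' @param fit optional pre-computed `wound_model_fit`; when supplied the
#'   training stages are skipped.
#' @param quiet suppress stage logging.
#' @return list (invisibly when writing) with `fit`, `scheme`, `labeled`,
#'   `ages`, `validation`, `births`, `month_histogram`, `seasonality`,
#'   `morphometrics` and `summary`. When `out_dir` is given, writes
#'   `labeled.csv`, `validation.csv`, `births.csv`, `month_histogram.csv`
#'   and `summary.json` there.
#' @export
run_pipeline <- function(input, out_dir = NULL,
                         boundaries = NULL,
                         season_months = c(9, 10, 11, 12, 1),
                         date_format = "%d/%m/%Y",
                         fit = NULL, quiet = FALSE) {
  log_ <- function(...) if (!quiet) message("[uwcager] ", ...)

  events <- .stage("read", {
    if (is.character(input)) read_captures(input, date_format) else
      validate_captures(input)
  })
  log_("read: ", nrow(events), " capture events, ",
       length(unique(events$shark_id)), " sharks")

  histories <- .stage("histories", build_histories(events))

  training_ids <- character(0)
  if (is.null(fit)) {
    pairs <- .stage("training", assemble_training_pairs(histories))
    training_ids <- attr(pairs, "anchor_ids")
    log_("training: ", nrow(pairs), " open-wound observations from ",
         length(training_ids), " days-old anchored sharks (",
         attr(pairs, "n_closed_excluded"), " closed-wound obs excluded)")
    fit <- .stage("fit", fit_wound_models(pairs))
    log_("fit: area model by ", fit$method_area, ", perimeter model by ",
         fit$method_perim)
  }

  if (is.null(boundaries)) {
    boundaries <- round(closure_age(fit)$day * c(1, 2, 3) / 3)
  }
  scheme <- .stage("scheme", derive_scheme(fit, boundaries))
  cl <- scheme$closure
  log_(sprintf("scheme: crit area %.3f cm^2, crit perimeter %.2f cm, closure day %d",
               scheme$crit_area_report, scheme$crit_perimeter_report, cl$day))

  labeled <- .stage("classify", classify_cohort(events, scheme))
  counts <- attr(labeled, "counts")
  log_("classify: counts ", paste(names(counts), counts, sep = "=",
                                  collapse = ", "))

  ages <- .stage("age", estimate_age(labeled, fit))

  val <- .stage("validate", validate_cohort(histories, fit, training_ids))
  vsum <- if (nrow(val$records) >= 2) summarize_validation(val$records) else
    list(mean_abs_diff = NA_real_, sd_abs_diff = NA_real_,
         n = nrow(val$records), mean_days = NA_real_, sd_days = NA_real_)
  log_("validate: ", nrow(val$records), " recapture pairs scored, ",
       nrow(val$exclusions), " excluded")

  births <- .stage("parturition", backcalculate(labeled, scheme))
  hist_df <- month_distribution(births)
  season_rows <- hist_df[hist_df$month %in% season_months, , drop = FALSE]
  seas <- if (nrow(season_rows) >= 2) {
    seasonality_test(season_rows$count)
  } else NULL
  log_("parturition: ", nrow(births), " estimates (",
       attr(births, "n_skipped_uwc4"), " juveniles skipped)")

  morpho <- .stage("morphometrics", {
    rec <- condition_records(labeled)
    if (nrow(rec) >= 4 && length(unique(rec$uwc)) >= 2) {
      res <- lapply(c("pcl", "mass", "k"), function(r)
        suppressWarnings(compare_groups(rec, r)))
      names(res) <- c("pcl", "mass", "k")
      res
    } else NULL
  })

  summary <- list(
    coefficients = list(a0 = fit$a0, a1 = fit$a1, b0 = fit$b0, b1 = fit$b1),
    critical_values = list(area_cm2 = scheme$crit_area_report,
                           perimeter_cm = scheme$crit_perimeter_report),
    closure_day = cl$day,
    class_counts = as.list(counts),
    validation = list(mean_abs_diff = vsum$mean_abs_diff,
                      sd_abs_diff = vsum$sd_abs_diff, n = vsum$n),
    month_histogram = stats::setNames(as.list(hist_df$count),
                                      hist_df$month_name),
    seasonality = seas,
    morphometrics = if (is.null(morpho)) NULL else
      lapply(morpho, function(m) list(f = m$anova$f, df1 = m$anova$df1,
                                      df2 = m$anova$df2,
                                      p_value = m$anova$p_value)),
    counts = list(events = nrow(events),
                  sharks = length(unique(events$shark_id)),
                  training_sharks = length(training_ids),
                  validation_pairs = nrow(val$records),
                  parturition_estimates = nrow(births))
  )
  check_summary(summary)

  bundle <- list(fit = fit, scheme = scheme, labeled = labeled, ages = ages,
                 validation = val, births = births,
                 month_histogram = hist_df, seasonality = seas,
                 morphometrics = morpho, summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    lab_out <- cbind(labeled, ages)
    lab_out$date <- format(lab_out$date, date_format)
    utils::write.csv(lab_out, file.path(out_dir, "labeled.csv"),
                     row.names = FALSE, na = "")
    vr <- val$records
    vr$initial_date <- format(vr$initial_date, date_format)
    vr$recapture_date <- format(vr$recapture_date, date_format)
    utils::write.csv(vr, file.path(out_dir, "validation.csv"),
                     row.names = FALSE, na = "")
    b <- births
    b$capture_date <- format(b$capture_date, date_format)
    b$t0 <- format(b$t0, date_format)
    utils::write.csv(b, file.path(out_dir, "births.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(hist_df, file.path(out_dir, "month_histogram.csv"),
                     row.names = FALSE, na = "")
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    log_("wrote outputs to ", out_dir)
    return(invisible(bundle))
  }
  bundle
}
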