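# End-to-end analysis: distribution summaries, per-endpoint discrimination
# blocks (ROC, cutoff, 2x2 metrics, odds ratio, simple logistic fits) and
# the multivariate linear model on mRS.

.endpoint_block <- function(scores, labels, cutoff_mode, conf_level = 0.95) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    return(list(estimable = FALSE,
                reason = "endpoint has a single class in this cohort"))
  }
  roc <- roc_auc(scores, labels, conf_level)
  cutoff <- if (identical(cutoff_mode, "auto")) youden_cutoff(roc)
            else as.numeric(cutoff_mode)
  tab <- two_by_two(scores, labels, cutoff)
  list(
    estimable = TRUE,
    auc = roc$auc, auc_ci_low = roc$auc_ci_low, auc_ci_high = roc$auc_ci_high,
    auc_p = roc$p_value,
    cutoff = cutoff, cutoff_rule = "positive iff score > cutoff",
    table = list(tp = tab$tp, fp = tab$fp, fn = tab$fn, tn = tab$tn),
    metrics = diagnostic_metrics(tab),
    odds_ratio = odds_ratio(tab, conf_level)
  )
}

#' Analyze a scored cohort
#'
#' Runs the full inferential stage on a table that already carries the
#' LODS totals, EBI assessment, CCI and outcomes: distribution summaries
#' with order-statistic median CIs, ROC/cutoff/2x2/odds-ratio blocks for
#' the three endpoints (severe EBI, unfavorable outcome mRS > 2,
#' in-hospital death) using the LODS total as the score, simple logistic
#' fits of each endpoint on LODS with and without the GCS component, and
#' the multivariate linear model of mRS on age, treatment, LODS, EBI
#' grade and CCI.
#'
#' @param scored A data frame with columns `lods_total`,
#'   `lods_without_gcs`, `ebi_grade`, `severe_ebi`, `mrs`,
#'   `died_in_hospital`, `age`, `treatment`, `cci`.
#' @param cutoff `"auto"` (Youden-optimal) or a numeric cutoff for the
#'   2x2 blocks.
#' @return A list of class `ebi_analysis` with elements `summary`,
#'   `endpoints`, `univariate`, `multivariate`, `meta`.
#' @export
analyze_cohort <- function(scored, cutoff = "auto") {
  need <- c("lods_total", "lods_without_gcs", "ebi_grade", "severe_ebi",
            "mrs", "died_in_hospital", "age", "treatment", "cci")
  absent <- setdiff(need, names(scored))
  if (length(absent) > 0) {
    stop("scored table is missing column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  n <- nrow(scored)
  favorable <- dichotomize_outcome(scored$mrs)
  endpoints <- list(
    severe_ebi = as.integer(scored$severe_ebi),
    unfavorable_outcome = as.integer(!favorable),
    in_hospital_death = as.integer(scored$died_in_hospital)
  )
  summary <- list(
    n = n,
    ebi_grade_freq = as.list(table(factor(scored$ebi_grade, levels = 1:5))),
    lods_freq = as.list(table(scored$lods_total)),
    mrs_freq = as.list(table(factor(scored$mrs, levels = 0:6))),
    severe_ebi_pct = 100 * mean(scored$severe_ebi),
    favorable_pct = 100 * mean(favorable),
    mortality_pct = 100 * mean(scored$died_in_hospital),
    median_ebi = median_with_ci(scored$ebi_grade),
    median_lods = median_with_ci(scored$lods_total)
  )
  blocks <- lapply(endpoints, function(lab) {
    .endpoint_block(scored$lods_total, lab, cutoff)
  })
  uni <- lapply(endpoints, function(lab) {
    if (length(unique(lab)) < 2) {
      return(list(estimable = FALSE,
                  reason = "endpoint has a single class in this cohort"))
    }
    list(
      estimable = TRUE,
      lods_with_gcs = logistic_fit(scored$lods_total, lab, "lods_total"),
      lods_without_gcs = logistic_fit(scored$lods_without_gcs, lab,
                                      "lods_without_gcs")
    )
  })
  mv <- scored
  mv$treatment_clipping <- as.integer(mv$treatment == "clipping")
  multivariate <- ols_multivariate(
    mv, "mrs",
    c("age", "treatment_clipping", "lods_total", "ebi_grade", "cci"))
  structure(list(
    summary = summary,
    endpoints = blocks,
    univariate = uni,
    multivariate = multivariate,
    meta = list(
      package_version = as.character(utils::packageVersion("lodsebi")),
      cutoff_mode = if (identical(cutoff, "auto")) "auto (Youden)"
                    else as.numeric(cutoff),
      auc_ci_method = "hanley-mcneil",
      median_ci_method = "order-statistic-binomial",
      favorable_rule = "mRS <= 2",
      severe_ebi_rule = "EBI grade >= 3"
    )
  ), class = "ebi_analysis")
}

#' @export
print.ebi_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Cohort analysis, n = %d\n", s$n))
  cat(sprintf("  severe EBI: %.1f%%   favorable outcome: %.1f%%   in-hospital mortality: %.1f%%\n",
              s$severe_ebi_pct, s$favorable_pct, s$mortality_pct))
  cat(sprintf("  median EBI grade %.0f (%.0f%% CI %.2f-%.2f), median LODS %.0f\n",
              s$median_ebi$median, 100 * s$median_ebi$conf_level,
              s$median_ebi$ci_low, s$median_ebi$ci_high,
              s$median_lods$median))
  for (nm in names(x$endpoints)) {
    b <- x$endpoints[[nm]]
    if (!isTRUE(b$estimable)) {
      cat(sprintf("  %s: not estimable (%s)\n", nm, b$reason))
      next
    }
    m <- b$metrics
    cat(sprintf("  %s: AUC %.2f (CI %.2f-%.2f), cutoff %g, sens %.0f%%, spec %.0f%%, PPV %.0f%%, NPV %.0f%%, OR %.2f\n",
                nm, b$auc, b$auc_ci_low, b$auc_ci_high, b$cutoff,
                100 * m$sensitivity, 100 * m$specificity, 100 * m$ppv,
                100 * m$npv, b$odds_ratio$or))
  }
  invisible(x)
}

#' Run the full scoring and analysis pipeline
#'
#' Reads (or accepts) a raw patient table, appends the LODS breakdown,
#' EBI assessment and Charlson index, and runs [analyze_cohort()].
#' Deterministic given the input and options.
#'
#' @param input A patient data frame or a path to a patient CSV.
#' @param cutoff `"auto"` or numeric, passed to [analyze_cohort()].
#' @param include_gcs Passed to [compute_lods()].
#' @param strict Passed to [read_patient_table()] when `input` is a path.
#' @return List with `scores` (the input with score columns appended) and
#'   `report` (the `ebi_analysis`).
#' @export
run_pipeline <- function(input, cutoff = "auto", include_gcs = TRUE,
                         strict = TRUE) {
  data <- if (is.character(input)) read_patient_table(input, strict = strict)
          else input
  scores <- cbind(data, compute_lods(data, include_gcs = include_gcs),
                  compute_ebi(data))
  scores$cci <- charlson_index(data)
  report <- analyze_cohort(scores, cutoff = cutoff)
  list(scores = scores, report = report)
}

# the report schema: required names per block, checked on every write
.report_schema <- list(
  top = c("summary", "endpoints", "univariate", "multivariate", "meta"),
  summary = c("n", "ebi_grade_freq", "lods_freq", "mrs_freq",
              "severe_ebi_pct", "favorable_pct", "mortality_pct",
              "median_ebi", "median_lods"),
  meta = c("package_version", "cutoff_mode", "auc_ci_method",
           "median_ci_method", "favorable_rule", "severe_ebi_rule")
)

#' Validate an analysis report against the committed schema
#'
#' @param report An `ebi_analysis` object or the list read back from its
#'   JSON rendering.
#' @return `TRUE` invisibly; errors when a required block or field is
#'   absent.
#' @export
validate_report <- function(report) {
  miss <- setdiff(.report_schema$top, names(report))
  if (length(miss) > 0) {
    stop("report is missing block(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  miss <- setdiff(.report_schema$summary, names(report$summary))
  if (length(miss) > 0) {
    stop("report summary is missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(.report_schema$meta, names(report$meta))
  if (length(miss) > 0) {
    stop("report meta is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Write an analysis report as JSON
#'
#' @param report An `ebi_analysis` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  validate_report(report)
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
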