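#' Full statistical analysis of a cohort
#'
#' Reproduces the study-style report for a two-group retinal cohort, eye by
#' eye (left and right eyes analysed separately throughout): baseline group
#' comparisons (pooled t-tests with 95% CIs and significance stars),
#' disease-coefficient linear regressions with the
#' adjusted-R-squared-and-significance confounder rule, a Cook's-distance
#' robustness refit, residual diagnostics, and the same pair of tables for
#' annualised rates of change.
#'
#' @param baseline Wide baseline outcome table: columns \code{subject_id},
#'   \code{eye}, then one column per outcome (the [simulate_cohort()]
#'   baseline schema).
#' @param rates Long rates table from [rates_table()] (may be NULL to skip
#'   the longitudinal stage).
#' @param subjects Subject table with \code{subject_id}, \code{group},
#'   \code{age}, \code{sex}.
#' @param confounders Apply the confounder-selection rule (default TRUE);
#'   if FALSE every model uses disease + age + sex.
#' @param robustness Run the influential-point refit (default TRUE).
#' @param fdr Add Benjamini-Hochberg adjusted p-values per table (default
#'   FALSE; the primary analysis is deliberately unadjusted).
#' @return A \code{morpho_report}: list of data.frames
#'   \code{baseline_comparison}, \code{baseline_regression},
#'   \code{rate_summary}, \code{rate_regression}, and \code{audit} (the
#'   confounder audit trail).
#' @export
analyze_cohort <- function(baseline, rates = NULL, subjects,
                           confounders = TRUE, robustness = TRUE,
                           fdr = FALSE) {
  stopifnot(is.data.frame(baseline),
            all(c("subject_id", "eye") %in% names(baseline)),
            is.data.frame(subjects),
            all(c("subject_id", "group", "age", "sex") %in% names(subjects)))
  outcomes <- setdiff(names(baseline), c("subject_id", "eye"))
  if (!length(outcomes)) stop("baseline table has no outcome columns")

  long_base <- do.call(rbind, lapply(outcomes, function(o) {
    data.frame(subject_id = baseline$subject_id, eye = baseline$eye,
               outcome = o, value = baseline[[o]], stringsAsFactors = FALSE)
  }))
  res_base <- analyze_long(long_base, subjects, confounders, robustness)
  tag_audit <- function(audit, stage) {
    if (is.null(audit) || !NROW(audit)) return(NULL)
    cbind(stage = stage, audit)
  }
  out <- list(baseline_comparison = res_base$comparison,
              baseline_regression = res_base$regression,
              audit = tag_audit(res_base$audit, "baseline"))

  if (!is.null(rates) && nrow(rates)) {
    stopifnot(all(c("subject_id", "eye", "outcome", "rate") %in%
                  names(rates)))
    long_rate <- data.frame(subject_id = rates$subject_id, eye = rates$eye,
                            outcome = rates$outcome, value = rates$rate,
                            stringsAsFactors = FALSE)
    res_rate <- analyze_long(long_rate, subjects, confounders, robustness,
                             summary_stat = "median")
    out$rate_summary <- res_rate$comparison
    out$rate_regression <- res_rate$regression
    out$audit <- rbind(out$audit, tag_audit(res_rate$audit, "rate"))
  } else {
    out$rate_summary <- NULL
    out$rate_regression <- NULL
  }

  if (fdr) {
    for (tab in c("baseline_comparison", "baseline_regression",
                  "rate_summary", "rate_regression")) {
      if (is.null(out[[tab]])) next
      pcol <- intersect(c("p_value", "disease_p"), names(out[[tab]]))[1]
      if (!is.na(pcol))
        out[[tab]]$p_bh <- stats::p.adjust(out[[tab]][[pcol]],
                                           method = "BH")
    }
  }
  structure(out, class = "morpho_report")
}

# Shared per-(outcome, eye) analysis over a long value table.
analyze_long <- function(long, subjects, confounders, robustness,
                         summary_stat = "mean") {
  long$group <- subjects$group[match(long$subject_id, subjects$subject_id)]
  long$age <- subjects$age[match(long$subject_id, subjects$subject_id)]
  long$sex <- subjects$sex[match(long$subject_id, subjects$subject_id)]
  comp <- list(); regr <- list(); audit <- list()
  for (o in unique(long$outcome)) for (eye in sort(unique(long$eye))) {
    d <- long[long$outcome == o & long$eye == eye & !is.na(long$value), ]
    if (nrow(d) < 4) next
    ms <- d$value[d$group == "MS"]; hv <- d$value[d$group == "HV"]
    if (length(ms) < 2 || length(hv) < 2) next
    tt <- ttest_two_sample(ms, hv)
    comp[[length(comp) + 1]] <- data.frame(
      outcome = o, eye = eye,
      n_ms = length(ms), n_hv = length(hv),
      ms_center = if (summary_stat == "median") stats::median(ms) else mean(ms),
      hv_center = if (summary_stat == "median") stats::median(hv) else mean(hv),
      ms_se = stats::sd(ms) / sqrt(length(ms)),
      hv_se = stats::sd(hv) / sqrt(length(hv)),
      ms_iqr = stats::IQR(ms), hv_iqr = stats::IQR(hv),
      difference = tt$difference, ci_lo = tt$ci95[1], ci_hi = tt$ci95[2],
      p_value = tt$p_value, stars = tt$stars, stringsAsFactors = FALSE)

    cov <- data.frame(disease = as.numeric(d$group == "MS"),
                      age = d$age, sex = as.numeric(d$sex == "F"))
    fit_res <- if (confounders) {
      sel <- select_confounders(d$value, cov)
      audit[[length(audit) + 1]] <- cbind(outcome = o, eye = eye, sel$audit)
      sel
    } else list(include = c("disease", "age", "sex"),
                fit = fit_linear_model(d$value, cov))
    fit <- fit_res$fit
    diag <- residual_diagnostics(fit)
    rob <- if (robustness)
      tryCatch(robustness_refit(fit), error = function(e) NULL) else NULL
    regr[[length(regr) + 1]] <- data.frame(
      outcome = o, eye = eye, n = fit$n,
      included = paste(fit$included, collapse = "+"),
      disease_coef = fit$coefficients["disease", 1],
      disease_se = fit$coefficients["disease", 2],
      disease_p = fit$coefficients["disease", 4],
      stars = p_stars(fit$coefficients["disease", 4]),
      adjusted_r2 = fit$adjusted_r2, model_p = fit$model_p,
      shapiro_p = diag$shapiro_p, skewness = diag$skewness,
      n_removed = if (is.null(rob)) NA_integer_ else length(rob$removed),
      disease_coef_robust = if (is.null(rob)) NA_real_ else
        rob$refit$coefficients["disease", 1],
      disease_p_robust = if (is.null(rob)) NA_real_ else
        rob$refit$coefficients["disease", 4],
      stringsAsFactors = FALSE)
  }
  list(comparison = do.call(rbind, comp),
       regression = do.call(rbind, regr),
       audit = if (length(audit)) do.call(rbind, audit) else
         data.frame())
}

#' @export
print.morpho_report <- function(x, ...) {
  cat("Cohort morphometry report\n")
  cat(sprintf("  baseline comparisons: %d rows; regressions: %d rows\n",
              NROW(x$baseline_comparison), NROW(x$baseline_regression)))
  if (!is.null(x$rate_regression))
    cat(sprintf("  rate summaries: %d rows; rate regressions: %d rows\n",
                NROW(x$rate_summary), NROW(x$rate_regression)))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' One CSV per table plus a JSON manifest listing the files written.
#'
#' @param report A \code{morpho_report}.
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (tab in c("baseline_comparison", "baseline_regression",
                "rate_summary", "rate_regression", "audit")) {
    if (is.null(report[[tab]]) || !NROW(report[[tab]])) next
    p <- file.path(dir, paste0(tab, ".csv"))
    utils::write.csv(report[[tab]], p, row.names = FALSE)
    files[[tab]] <- basename(p)
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(tables = files,
                            generated_by = "retmorph",
                            n_tables = length(files)),
                       manifest, auto_unbox = TRUE)
  invisible(manifest)
}
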