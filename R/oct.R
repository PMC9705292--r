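oct_schema <- function() {
  c("subject_id", "eye", "visit_date", "quality_score", "art",
    "rnfl_global", "rnfl_t", "rnfl_ti", "rnfl_ts", "rnfl_n", "rnfl_ni",
    "rnfl_ns", "macular_volume", "pregnancy_visit")
}

#' Load OCT summary records from CSV
#'
#' Expects the documented schema (see [simulate_visits()] /
#' [write_cohort()]): subject_id, eye, visit_date (ISO-8601), quality_score,
#' art, the seven rnfl_* region thicknesses in um, macular_volume in mm^3,
#' pregnancy_visit. Missing numeric cells become NA, never zero; malformed
#' dates or numbers raise an error naming the offending row.
#'
#' @param path CSV file path.
#' @return data.frame of OCT records with parsed dates.
#' @export
load_oct_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(oct_schema(), names(df))
  if (length(missing_cols))
    stop("OCT CSV is missing columns: ", paste(missing_cols, collapse = ", "))
  df <- df[, oct_schema()]
  if (nrow(df) == 0) {
    df$visit_date <- as.Date(character(0))
    for (cc in c("quality_score", "art", "rnfl_global", "rnfl_t", "rnfl_ti",
                 "rnfl_ts", "rnfl_n", "rnfl_ni", "rnfl_ns",
                 "macular_volume"))
      df[[cc]] <- numeric(0)
    df$pregnancy_visit <- logical(0)
    return(df)
  }
  dates <- as.Date(df$visit_date, format = "%Y-%m-%d")
  # as.Date silently wraps some impossible dates; re-format to verify.
  bad <- is.na(dates) | format(dates, "%Y-%m-%d") != df$visit_date
  if (any(bad))
    stop(sprintf("unparseable visit_date %s in row %d",
                 df$visit_date[which(bad)[1]], which(bad)[1]))
  df$visit_date <- dates
  num_cols <- c("quality_score", "art", "rnfl_global", "rnfl_t", "rnfl_ti",
                "rnfl_ts", "rnfl_n", "rnfl_ni", "rnfl_ns", "macular_volume")
  for (cc in num_cols) {
    raw <- trimws(df[[cc]])
    val <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & raw != "" & raw != "NA" & is.na(val)
    if (any(bad))
      stop(sprintf("malformed numeric value '%s' in column %s, row %d",
                   raw[which(bad)[1]], cc, which(bad)[1]))
    val[raw == ""] <- NA_real_
    df[[cc]] <- val
  }
  bad_th <- num_cols[3:10]
  for (cc in bad_th) {
    neg <- !is.na(df[[cc]]) & df[[cc]] <= 0
    if (any(neg))
      stop(sprintf("non-positive thickness in column %s, row %d",
                   cc, which(neg)[1]))
  }
  df$pregnancy_visit <- toupper(trimws(df$pregnancy_visit)) %in%
    c("TRUE", "T", "1", "YES")
  df
}

#' Apply the study's eligibility and quality exclusions
#'
#' Rules are applied in order, a record being attributed to the first rule
#' that removes it: (1) subjects with retinal pathology or high myopia
#' (refractive error of -10 dioptres or worse) lose all records;
#' (2) MS subjects with a history of optic neuritis lose all records;
#' (3) records with quality score below 25 are removed (25 itself is
#' retained: a minimum of 25 means >= 25); (4) pregnancy-flagged visits are
#' retained but marked ineligible for follow-up (rate-of-change) analyses.
#'
#' @param records OCT record data.frame (see [load_oct_records()]).
#' @param subjects Subject table with subject_id, group,
#'   optic_neuritis_history, retinal_pathology, high_myopia.
#' @return List with \code{records} (surviving records plus a logical
#'   \code{followup_eligible} column) and \code{report}, a
#'   \code{filter_report}: per-rule removal counts whose sum plus the
#'   surviving count equals the input count.
#' @export
apply_exclusions <- function(records, subjects) {
  orphan <- !(records$subject_id %in% subjects$subject_id)
  if (any(orphan))
    stop("records reference unknown subjects: ",
         paste(unique(records$subject_id[orphan]), collapse = ", "))
  idx <- match(records$subject_id, subjects$subject_id)
  n_in <- nrow(records)

  rule1 <- subjects$retinal_pathology[idx] | subjects$high_myopia[idx]
  rule2 <- !rule1 & subjects$group[idx] == "MS" &
    subjects$optic_neuritis_history[idx]
  rule3 <- !rule1 & !rule2 & !is.na(records$quality_score) &
    records$quality_score < 25
  keep <- !(rule1 | rule2 | rule3)

  out <- records[keep, , drop = FALSE]
  out$followup_eligible <- !out$pregnancy_visit
  report <- structure(list(
    input = n_in,
    removed_pathology_or_myopia = sum(rule1),
    removed_optic_neuritis = sum(rule2),
    removed_low_quality = sum(rule3),
    flagged_pregnancy_followup_only = sum(out$pregnancy_visit),
    surviving = nrow(out)), class = "filter_report")
  list(records = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Exclusion report: %d records in\n",
    "  removed, retinal pathology / high myopia: %d\n",
    "  removed, optic neuritis history (MS):     %d\n",
    "  removed, quality score < 25:              %d\n",
    "  surviving: %d (of which %d pregnancy visits, baseline-only)\n"),
    x$input, x$removed_pathology_or_myopia, x$removed_optic_neuritis,
    x$removed_low_quality, x$surviving, x$flagged_pregnancy_followup_only))
  invisible(x)
}

#' Annualised rate of change for one subject-eye series
#'
#' Ordinary least-squares slope of the outcome against years since the
#' first usable visit (divisor 365.25 days/year); with exactly two visits
#' this is the two-point difference quotient. Mirrors longitudinal designs
#' with irregular inter-visit intervals.
#'
#' @param dates Visit dates (Date or numeric days).
#' @param values Outcome values at those visits.
#' @return Slope per year, or NA if fewer than 2 usable visits.
#' @export
annual_rate <- function(dates, values) {
  ok <- !is.na(values) & !is.na(dates)
  if (sum(ok) < 2) return(NA_real_)
  yrs <- as.numeric(dates[ok] - min(dates[ok])) / 365.25
  if (diff(range(yrs)) == 0) return(NA_real_)
  # closed-form simple-regression slope (equals lm(values ~ yrs))
  v <- values[ok]
  sum((yrs - mean(yrs)) * (v - mean(v))) / sum((yrs - mean(yrs))^2)
}

#' Per-subject annualised rates for every outcome
#'
#' Uses only follow-up-eligible records (pregnancy visits excluded);
#' subject-eyes with fewer than two usable visits contribute nothing.
#'
#' @param records Filtered records from [apply_exclusions()].
#' @param outcomes Outcome columns to annualise; default [oct_outcomes()].
#' @return Long data.frame: subject_id, eye, outcome, rate.
#' @export
rates_table <- function(records, outcomes = oct_outcomes()) {
  if (!"followup_eligible" %in% names(records))
    records$followup_eligible <- TRUE
  rec <- records[records$followup_eligible, , drop = FALSE]
  empty <- data.frame(subject_id = character(0), eye = character(0),
                      outcome = character(0), rate = numeric(0))
  if (!nrow(rec)) return(empty)
  key <- paste(rec$subject_id, rec$eye)
  groups <- split(seq_len(nrow(rec)), factor(key, levels = unique(key)))
  dates <- as.numeric(rec$visit_date)
  ids <- character(0); eyes <- character(0)
  outs <- character(0); rates <- numeric(0)
  for (g in groups) {
    for (o in outcomes) {
      r <- annual_rate(dates[g], rec[[o]][g])
      if (!is.na(r)) {
        ids <- c(ids, rec$subject_id[g[1]])
        eyes <- c(eyes, rec$eye[g[1]])
        outs <- c(outs, o)
        rates <- c(rates, r)
      }
    }
  }
  if (!length(ids)) return(empty)
  data.frame(subject_id = ids, eye = eyes, outcome = outs, rate = rates,
             stringsAsFactors = FALSE)
}

#' Baseline group summary: mean and standard error per region
#'
#' Baseline is each subject-eye's earliest surviving record. SE is the
#' sample SD over subjects divided by sqrt(n); reported NA when n < 2.
#'
#' @param records Filtered records from [apply_exclusions()].
#' @param subjects Subject table (for group membership).
#' @param outcomes Outcome columns; default [oct_outcomes()].
#' @return data.frame: group, eye, outcome, n, mean, se.
#' @export
baseline_table <- function(records, subjects, outcomes = oct_outcomes()) {
  base <- baseline_records(records)
  base$group <- subjects$group[match(base$subject_id, subjects$subject_id)]
  groups <- unique(subjects$group)
  rows <- list()
  for (g in groups) {
    if (!any(base$group == g))
      stop("no baseline records for group ", g)
    for (eye in unique(base$eye)) for (o in outcomes) {
      v <- base[[o]][base$group == g & base$eye == eye]
      v <- v[!is.na(v)]
      rows[[length(rows) + 1]] <- data.frame(
        group = g, eye = eye, outcome = o, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        se = if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Earliest surviving record per subject-eye.
baseline_records <- function(records) {
  ord <- order(records$subject_id, records$eye, records$visit_date)
  rec <- records[ord, , drop = FALSE]
  first <- !duplicated(rec[, c("subject_id", "eye")])
  rec[first, , drop = FALSE]
}
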