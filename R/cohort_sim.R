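#' Outcome names used by the cohort simulator and analysis stage
#'
#' @return Character vectors of outcome keys: seven peripapillary RNFL
#'   regions plus macular volume (\code{oct_outcomes}), and the eight
#'   quadrant-by-type peripheral vessel widths (\code{vessel_outcomes}).
#' @export
oct_outcomes <- function() {
  c("rnfl_global", "rnfl_t", "rnfl_ti", "rnfl_ts",
    "rnfl_n", "rnfl_ni", "rnfl_ns", "macular_volume")
}

#' @rdname oct_outcomes
#' @export
vessel_outcomes <- function() {
  c("width_artery_ti", "width_vein_ti", "width_artery_ts", "width_vein_ts",
    "width_artery_ni", "width_vein_ni", "width_artery_ns", "width_vein_ns")
}

#' Cohort generator configuration
#'
#' Defines the data-generating model for a two-group (MS vs healthy
#' volunteer) cohort with cross-sectional baseline outcomes and irregular
#' longitudinal follow-up. Each baseline outcome is
#' \code{intercept + beta_disease * 1[MS] + beta_age * age +
#' beta_sex * 1[female] + N(0, noise_sd)}, drawn independently for the two
#' eyes of every subject. Follow-up visits add
#' \code{annual_slope * years + N(0, visit_noise_sd)} on top of the
#' subject's baseline value.
#'
#' Defaults encode a cohort of 72 MS / 80 HV subjects with effect sizes,
#' baseline levels, slopes, and visit-interval ranges at the magnitudes
#' reported for MS retinal morphometry: e.g. a -10 um disease effect on
#' global RNFL thickness, a -0.0079 mm disease effect on nasal-inferior
#' artery width, an extra -0.98 um/year of global RNFL thinning and
#' -0.047 mm^3/year of macular-volume loss in MS, with baseline-to-final
#' spans of 196--672 days (MS, 1--5 visits) and 227--802 days (HV, 1--3
#' visits).
#'
#' @param n_per_group Named vector \code{c(MS=, HV=)} of subjects per group.
#' @param age_range List of per-group age ranges in years.
#' @param p_female Named vector of female proportions per group.
#' @param subtype_probs Probabilities of RRMS/PPMS/SPMS among MS subjects.
#' @param intercepts,beta_disease,beta_age,beta_sex Named numeric vectors
#'   keyed by outcome (see [oct_outcomes()] and [vessel_outcomes()]);
#'   partial vectors override the defaults. Intercepts are the outcome at
#'   age 0, male, healthy; defaults are back-computed so that group means at
#'   a typical age land at healthy-eye reference values.
#' @param annual_slope List with elements \code{MS} and \code{HV}: named
#'   per-outcome change per year for the OCT outcomes.
#' @param noise_sd,visit_noise_sd Named per-outcome measurement noise SDs:
#'   between-subject residual at baseline, and visit-level repeatability.
#' @param visit_interval_range List of per-group (min, max) days between the
#'   baseline and final visit.
#' @param visits_range List of per-group (min, max) visit counts.
#' @param p_optic_neuritis Probability of a history of optic neuritis among
#'   MS subjects (these are later excluded from analysis).
#' @param p_pregnancy Probability that an HV female with follow-up has one
#'   pregnancy-flagged follow-up visit.
#' @param quality_mean,quality_sd OCT quality-score distribution.
#' @param seed Integer; fixes all generation reproducibly.
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_per_group = c(MS = 72, HV = 80),
                          age_range = list(MS = c(20, 79), HV = c(23, 73)),
                          p_female = c(MS = 53 / 72, HV = 61 / 80),
                          subtype_probs = c(RRMS = 62 / 71, PPMS = 2 / 71,
                                            SPMS = 7 / 71),
                          intercepts = NULL, beta_disease = NULL,
                          beta_age = NULL, beta_sex = NULL,
                          annual_slope = NULL,
                          noise_sd = NULL, visit_noise_sd = NULL,
                          visit_interval_range = list(MS = c(196, 672),
                                                      HV = c(227, 802)),
                          visits_range = list(MS = c(1, 5), HV = c(1, 3)),
                          p_optic_neuritis = 0.12, p_pregnancy = 0.03,
                          quality_mean = 32, quality_sd = 4, seed = 1) {
  outs <- c(oct_outcomes(), vessel_outcomes())

  ref_level <- c(rnfl_global = 98.5, rnfl_t = 70.5, rnfl_ti = 143.5,
                 rnfl_ts = 136, rnfl_n = 76, rnfl_ni = 111.5,
                 rnfl_ns = 103.5, macular_volume = 8.67,
                 width_artery_ti = 0.0955, width_vein_ti = 0.1115,
                 width_artery_ts = 0.1040, width_vein_ts = 0.1180,
                 width_artery_ni = 0.0710, width_vein_ni = 0.0830,
                 width_artery_ns = 0.0780, width_vein_ns = 0.0920)
  bd <- c(rnfl_global = -10, rnfl_t = -12, rnfl_ti = -12, rnfl_ts = -8,
          rnfl_n = -10, rnfl_ni = -8, rnfl_ns = -8, macular_volume = -0.29,
          width_artery_ti = -0.0044, width_vein_ti = 1e-4,
          width_artery_ts = -7e-4, width_vein_ts = 4e-4,
          width_artery_ni = -0.0079, width_vein_ni = -0.0054,
          width_artery_ns = -0.0027, width_vein_ns = -0.0043)
  ba <- c(rnfl_global = -0.19, rnfl_t = -0.1, rnfl_ti = -0.1,
          rnfl_ts = -0.1, rnfl_n = -0.1, rnfl_ni = -0.1, rnfl_ns = -0.38,
          macular_volume = -0.002,
          stats::setNames(rep(0, 8), vessel_outcomes()))
  bs <- stats::setNames(rep(0, length(outs)), outs)
  ns <- c(rnfl_global = 11.2, rnfl_t = 12.5, rnfl_ti = 21, rnfl_ts = 18.8,
          rnfl_n = 16.5, rnfl_ni = 26.4, rnfl_ns = 20.1,
          macular_volume = 0.36,
          stats::setNames(rep(0.018, 8), vessel_outcomes()))
  vns <- c(stats::setNames(rep(2, 7), oct_outcomes()[1:7]),
           macular_volume = 0.05,
           stats::setNames(rep(0.004, 8), vessel_outcomes()))
  slope_hv <- c(rnfl_global = 0.35, rnfl_t = 0.35, rnfl_ti = 0,
                rnfl_ts = 0.48, rnfl_n = 0.38, rnfl_ni = 0.375,
                rnfl_ns = 0.2, macular_volume = 0.0065,
                stats::setNames(rep(0, 8), vessel_outcomes()))
  slope_disease <- c(rnfl_global = -0.98, rnfl_t = -0.8, rnfl_ti = 0.3,
                     rnfl_ts = -1.01, rnfl_n = -1.2, rnfl_ni = -1.32,
                     rnfl_ns = -1.11, macular_volume = -0.047,
                     stats::setNames(rep(0, 8), vessel_outcomes()))

  merge_named <- function(base, user) {
    if (!is.null(user)) base[names(user)] <- user
    base
  }
  bd <- merge_named(bd, beta_disease)
  ba <- merge_named(ba, beta_age)
  bs <- merge_named(bs, beta_sex)
  ns <- merge_named(ns, noise_sd)
  vns <- merge_named(vns, visit_noise_sd)
  ic <- ref_level - ba * 45  # reference levels hold at a typical age
  ic <- merge_named(ic, intercepts)
  if (is.null(annual_slope))
    annual_slope <- list(HV = slope_hv, MS = slope_hv + slope_disease)
  else {
    annual_slope$HV <- merge_named(slope_hv, annual_slope$HV)
    annual_slope$MS <- merge_named(slope_hv + slope_disease,
                                   annual_slope$MS)
  }

  stopifnot(all(ns >= 0), all(vns >= 0),
            all(n_per_group >= 1),
            all(vapply(age_range, function(r) diff(r) > 0, logical(1))),
            all(vapply(visit_interval_range, function(r) diff(r) > 0,
                       logical(1))),
            all(vapply(visits_range, function(r) r[2] >= r[1], logical(1))))

  structure(list(n_per_group = n_per_group, age_range = age_range,
                 p_female = p_female, subtype_probs = subtype_probs,
                 intercepts = ic, beta_disease = bd, beta_age = ba,
                 beta_sex = bs, annual_slope = annual_slope,
                 noise_sd = ns, visit_noise_sd = vns,
                 visit_interval_range = visit_interval_range,
                 visits_range = visits_range,
                 p_optic_neuritis = p_optic_neuritis,
                 p_pregnancy = p_pregnancy,
                 quality_mean = quality_mean, quality_sd = quality_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a cross-sectional cohort
#'
#' Draws subjects (group, age, sex, subtype, exclusion flags) and baseline
#' outcomes for both eyes under the configured linear model. With the seed
#' fixed, output is reproducible bit-for-bit.
#'
#' @param config A [cohort_config()].
#' @return List with \code{subjects} (one row per subject: subject_id,
#'   group, age, sex, subtype, optic_neuritis_history, retinal_pathology,
#'   high_myopia) and \code{baseline} (one row per subject and eye with one
#'   column per outcome).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (any(config$n_per_group < 2))
    stop("n_per_group must be at least 2 in each group (no variance estimable)")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  subjects <- do.call(rbind, lapply(c("MS", "HV"), function(g) {
    n <- config$n_per_group[[g]]
    data.frame(
      subject_id = sprintf("%s%03d", g, seq_len(n)),
      group = g,
      age = round(stats::runif(n, config$age_range[[g]][1],
                               config$age_range[[g]][2]), 1),
      sex = ifelse(stats::rbinom(n, 1, config$p_female[[g]]) == 1, "F", "M"),
      subtype = if (g == "MS")
        sample(names(config$subtype_probs), n, replace = TRUE,
               prob = config$subtype_probs) else "none",
      optic_neuritis_history = if (g == "MS")
        stats::rbinom(n, 1, config$p_optic_neuritis) == 1 else FALSE,
      retinal_pathology = FALSE,
      high_myopia = FALSE,
      stringsAsFactors = FALSE)
  }))

  outs <- names(config$intercepts)
  baseline <- do.call(rbind, lapply(c("OD", "OS"), function(eye) {
    vals <- sapply(outs, function(o) {
      config$intercepts[[o]] +
        config$beta_disease[[o]] * (subjects$group == "MS") +
        config$beta_age[[o]] * subjects$age +
        config$beta_sex[[o]] * (subjects$sex == "F") +
        stats::rnorm(nrow(subjects), 0, config$noise_sd[[o]])
    })
    cbind(data.frame(subject_id = subjects$subject_id, eye = eye,
                     stringsAsFactors = FALSE),
          as.data.frame(vals))
  }))
  baseline <- baseline[order(baseline$subject_id, baseline$eye), ]
  rownames(baseline) <- NULL
  list(subjects = subjects, baseline = baseline)
}

#' Simulate longitudinal visits with irregular intervals
#'
#' For each subject the number of visits is drawn uniformly from the
#' group-specific range; when there is follow-up, the span between baseline
#' and final visit is drawn uniformly (in whole days) from the group's
#' interval range and any intermediate visits fall on uniformly drawn
#' distinct days within it, so the span is within the configured range by
#' construction. OCT outcomes evolve from the subject's baseline value at
#' the group- and region-specific annual slope, with visit-level
#' measurement noise; quality scores and ART metadata are attached, and an
#' occasional HV pregnancy flags one follow-up visit.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param config The same [cohort_config()].
#' @return A visit-level data.frame in the OCT record schema: subject_id,
#'   eye, visit_date, quality_score, art, the seven rnfl_* columns,
#'   macular_volume, pregnancy_visit.
#' @export
simulate_visits <- function(cohort, config) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed + 1L)

  subjects <- cohort$subjects
  baseline <- cohort$baseline
  base_key <- paste(baseline$subject_id, baseline$eye)
  outs <- oct_outcomes()
  pick <- function(x) if (length(x) == 1) x else sample(x, 1)
  acc_id <- list(); acc_eye <- list(); acc_date <- list()
  acc_q <- list(); acc_vals <- list(); acc_preg <- list()
  k <- 0L
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    g <- subjects$group[i]
    vr <- config$visits_range[[g]]
    n_vis <- pick(seq(vr[1], vr[2]))
    if (n_vis >= 2) {
      ir <- config$visit_interval_range[[g]]
      span <- pick(seq(ir[1], ir[2]))
      mids <- if (n_vis > 2)
        sort(sample(seq_len(span - 1), n_vis - 2)) else integer(0)
      days <- c(0, mids, span)
    } else days <- 0
    start <- as.Date("2018-01-01") + sample(0:364, 1)
    preg_visit <- 0L
    if (g == "HV" && subjects$sex[i] == "F" && n_vis >= 2 &&
        stats::rbinom(1, 1, config$p_pregnancy) == 1)
      preg_visit <- pick(2:n_vis)
    yrs <- days / 365.25
    for (eye in c("OD", "OS")) {
      brow <- match(paste(sid, eye), base_key)
      vals <- vapply(outs, function(o) {
        baseline[[o]][brow] + config$annual_slope[[g]][[o]] * yrs +
          stats::rnorm(n_vis, 0, config$visit_noise_sd[[o]])
      }, numeric(n_vis))
      k <- k + 1L
      acc_id[[k]] <- rep(sid, n_vis)
      acc_eye[[k]] <- rep(eye, n_vis)
      acc_date[[k]] <- as.numeric(start) + days
      acc_q[[k]] <- round(pmax(0, stats::rnorm(n_vis, config$quality_mean,
                                               config$quality_sd)), 1)
      acc_vals[[k]] <- matrix(vals, nrow = n_vis)
      acc_preg[[k]] <- seq_len(n_vis) == preg_visit
    }
  }
  vals_all <- do.call(rbind, acc_vals)
  colnames(vals_all) <- outs
  out <- cbind(
    data.frame(subject_id = unlist(acc_id), eye = unlist(acc_eye),
               visit_date = as.Date(unlist(acc_date),
                                    origin = "1970-01-01"),
               quality_score = unlist(acc_q), art = 100L,
               stringsAsFactors = FALSE),
    as.data.frame(vals_all),
    data.frame(pregnancy_visit = unlist(acc_preg)))
  rownames(out) <- NULL
  out
}

#' Write cohort tables and configuration to disk
#'
#' Subjects and visit/baseline tables go to CSV; the full generator
#' configuration is echoed as YAML for provenance.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param visits Optional output of [simulate_visits()].
#' @param config The [cohort_config()] used.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, visits = NULL, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(subjects = file.path(dir, "subjects.csv"),
             baseline = file.path(dir, "baseline.csv"),
             config = file.path(dir, "cohort_config.yaml"))
  utils::write.csv(cohort$subjects, paths["subjects"], row.names = FALSE)
  utils::write.csv(cohort$baseline, paths["baseline"], row.names = FALSE)
  cfg <- unclass(config)
  cfg$annual_slope <- lapply(cfg$annual_slope, as.list)
  yaml::write_yaml(lapply(cfg, function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x),
    paths["config"])
  if (!is.null(visits)) {
    paths <- c(paths, visits = file.path(dir, "visits.csv"))
    v <- visits
    v$visit_date <- format(v$visit_date, "%Y-%m-%d")
    utils::write.csv(v, paths["visits"], row.names = FALSE)
  }
  invisible(paths)
}
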