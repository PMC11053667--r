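# Seeded synthetic-data generator.
#
# Produces every input the pipeline consumes with the statistical structure
# the analysis assumes: truncated-normal haematocrit, blood/plasma
# partitioning per analyte, multiplicative lognormal measurement error
# (constant CV), per-lot calibration-slope variation, lognormal MPR with
# optional clearance-shift outliers.
#
# Stage seeds: each generator reseeds deterministically from config$seed
# plus a fixed stage offset (cohort +0, paired +1, calibration +2, QC +3),
# so stages are individually reproducible and mutually independent.

#' Configuration of the synthetic study
#'
#' Defaults describe the emulated study population and assay: haematocrit
#' normal (mean 0.42, SD 0.05) truncated to \[0.25, 0.55\]; partition
#' coefficients 1.57 (parent) and 0 (glucuronide, excluded from cells);
#' 5% multiplicative lognormal measurement CV; calibration slope/intercept
#' 0.1683/-0.0012 (parent) and 1.1243/0.0124 (metabolite) response ratio
#' per ug/mL; 2% between-lot slope RSD; trough MPR lognormal with median
#' 0.32 and log-SD 0.45; daily doses drawn from
#' \{100, 200, 250, 300, 400\} mg; apparent oral clearance lognormal with
#' median 52 L/day and 40% CV (typical for adult lamotrigine, placing
#' troughs in the 2.5-15 ug/mL reference range).
#'
#' @param seed integer master seed.
#' @param n_subjects cohort size.
#' @param hct_mean,hct_sd,hct_range haematocrit distribution (fractions).
#' @param k_parent,k_metabolite blood-cell-to-plasma partition coefficients.
#' @param meas_cv multiplicative measurement CV (fraction).
#' @param cal_slope,cal_intercept named numeric vectors (PARENT,
#'   METABOLITE) of calibration parameters.
#' @param lot_slope_rsd between-lot relative SD of the calibration slope.
#' @param mpr_location median of the lognormal MPR distribution.
#' @param mpr_log_sd SD of log(MPR).
#' @param outlier_spec optional list of `list(subject = i, fold = f)`
#'   entries multiplying subject `i`'s MPR by `f` (a clearance fold-change:
#'   induction > 1, inhibition < 1).
#' @param cl_typical,cl_cv apparent clearance: lognormal median (L/day) and
#'   CV.
#' @param peak_trough_range peak/trough concentration ratio range
#'   (uniform draw per subject).
#' @param cal_levels calibration levels, ug/mL.
#' @param additive_floor additive error SD, ug/mL (0 = pure proportional
#'   error).
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_subjects = 9L,
                             hct_mean = 0.42, hct_sd = 0.05,
                             hct_range = c(0.25, 0.55),
                             k_parent = 1.57, k_metabolite = 0,
                             meas_cv = 0.05,
                             cal_slope = c(PARENT = 0.1683,
                                           METABOLITE = 1.1243),
                             cal_intercept = c(PARENT = -0.0012,
                                               METABOLITE = 0.0124),
                             lot_slope_rsd = 0.02,
                             mpr_location = 0.32, mpr_log_sd = 0.45,
                             outlier_spec = NULL,
                             cl_typical = 52, cl_cv = 0.4,
                             peak_trough_range = c(1.3, 1.8),
                             cal_levels = c(0.1, 0.25, 0.5, 0.75, 1, 5,
                                            7.5, 10, 12.5, 17.5, 20),
                             additive_floor = 0) {
  stopifnot(n_subjects >= 1L, hct_sd >= 0, meas_cv >= 0,
            lot_slope_rsd >= 0, mpr_log_sd >= 0, additive_floor >= 0,
            k_parent >= 0, k_metabolite >= 0,
            hct_range[1] > 0, hct_range[2] < 1,
            hct_range[1] < hct_range[2],
            all(analyte_ids() %in% names(cal_slope)),
            all(analyte_ids() %in% names(cal_intercept)))
  if (!is.null(outlier_spec)) {
    for (o in outlier_spec) {
      if (!all(c("subject", "fold") %in% names(o))) {
        stop("outlier_spec entries need 'subject' and 'fold'",
             call. = FALSE)
      }
      if (o$subject < 1 || o$subject > n_subjects) {
        stop("outlier_spec subject index ", o$subject, " out of range 1..",
             n_subjects, call. = FALSE)
      }
    }
  }
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 hct_mean = hct_mean, hct_sd = hct_sd,
                 hct_range = hct_range, k_parent = k_parent,
                 k_metabolite = k_metabolite, meas_cv = meas_cv,
                 cal_slope = cal_slope, cal_intercept = cal_intercept,
                 lot_slope_rsd = lot_slope_rsd,
                 mpr_location = mpr_location, mpr_log_sd = mpr_log_sd,
                 outlier_spec = outlier_spec, cl_typical = cl_typical,
                 cl_cv = cl_cv, peak_trough_range = peak_trough_range,
                 cal_levels = cal_levels, additive_floor = additive_floor),
            class = "synthetic_config")
}

# Mean-1 multiplicative lognormal noise with exact coefficient of
# variation cv; cv = 0 returns 1s.
ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(n, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

stage_seed <- function(config, offset) {
  set.seed((config$seed + offset) %% .Machine$integer.max)
}

#' Generate a synthetic patient cohort
#'
#' Draws per-subject dose, haematocrit, apparent clearance, trough parent
#' plasma concentration (dose / clearance, clamped to the 0.1-20 ug/mL
#' analytical range), a lognormal MPR (after applying any
#' `outlier_spec` clearance fold-changes), the metabolite plasma
#' concentration `MPR * parent`, and peak concentrations as a per-subject
#' uniform multiple of trough. Fully reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return `data.frame` with one row per subject: `subject_id`, `dose`,
#'   `hct`, `cl`, `mpr`, `parent_trough_pl`, `metabolite_trough_pl`,
#'   `parent_peak_pl`, `metabolite_peak_pl`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  stage_seed(config, 0L)
  n <- config$n_subjects
  dose <- sample(c(100, 200, 250, 300, 400), n, replace = TRUE)
  hct <- rtruncnorm1(n, config$hct_mean, config$hct_sd,
                     config$hct_range[1], config$hct_range[2])
  cl <- config$cl_typical * rlnorm(n, 0, sqrt(log(1 + config$cl_cv^2)))
  parent <- pmin(pmax(dose / cl, 0.1), 20)
  mpr <- rlnorm(n, log(config$mpr_location), config$mpr_log_sd)
  for (o in config$outlier_spec) {
    mpr[o$subject] <- mpr[o$subject] * o$fold
  }
  peak_fac <- runif(n, config$peak_trough_range[1],
                    config$peak_trough_range[2])
  data.frame(subject_id = as.character(seq_len(n)), dose = dose,
             hct = hct, cl = cl, mpr = mpr,
             parent_trough_pl = parent,
             metabolite_trough_pl = mpr * parent,
             parent_peak_pl = pmin(parent * peak_fac, 20),
             metabolite_peak_pl = pmin(mpr * parent * peak_fac, 20),
             stringsAsFactors = FALSE)
}

#' Generate paired DBS/plasma measurements from a cohort
#'
#' For every subject x analyte x timepoint the true blood concentration is
#' derived from the true plasma concentration by the partition model with
#' the analyte's coefficient; observed `c_b` and `c_pl` are the truths
#' multiplied by independent mean-1 lognormal noise with CV
#' `config$meas_cv`.
#'
#' @param cohort output of [generate_cohort()].
#' @param config a [synthetic_config()].
#' @return paired-measurement `data.frame` (columns `subject_id`,
#'   `analyte`, `timepoint`, `c_b`, `c_pl`, `hct`) with additional
#'   `true_c_b`, `true_c_pl` columns; `write_paired_table()` keeps only the
#'   schema columns if the extras are dropped beforehand.
#' @export
generate_paired <- function(cohort, config) {
  stopifnot(inherits(config, "synthetic_config"), nrow(cohort) >= 1L)
  stage_seed(config, 1L)
  k_of <- c(PARENT = config$k_parent, METABOLITE = config$k_metabolite)
  grid <- expand.grid(analyte = analyte_ids(),
                      timepoint = c("TROUGH", "PEAK"),
                      i = seq_len(nrow(cohort)),
                      stringsAsFactors = FALSE)
  truth_col <- ifelse(grid$analyte == "PARENT",
                      ifelse(grid$timepoint == "TROUGH",
                             "parent_trough_pl", "parent_peak_pl"),
                      ifelse(grid$timepoint == "TROUGH",
                             "metabolite_trough_pl", "metabolite_peak_pl"))
  true_pl <- vapply(seq_len(nrow(grid)), function(r) {
    cohort[[truth_col[r]]][grid$i[r]]
  }, numeric(1))
  hct <- cohort$hct[grid$i]
  true_b <- blood_from_plasma(true_pl, hct, k_of[grid$analyte])
  m <- nrow(grid)
  obs_b <- true_b * ln_noise(m, config$meas_cv)
  obs_pl <- true_pl * ln_noise(m, config$meas_cv)
  if (config$additive_floor > 0) {
    obs_b <- pmax(obs_b + rnorm(m, 0, config$additive_floor), 0)
    obs_pl <- pmax(obs_pl + rnorm(m, 0, config$additive_floor), 0)
  }
  # expand.grid varies analyte fastest and subject slowest, so rows are
  # already grouped by subject
  data.frame(subject_id = cohort$subject_id[grid$i],
             analyte = grid$analyte, timepoint = grid$timepoint,
             c_b = obs_b, c_pl = obs_pl, hct = hct,
             true_c_b = true_b, true_c_pl = true_pl,
             stringsAsFactors = FALSE)
}

#' Generate calibration observations
#'
#' Per analyte, lot and day: the lot's slope is the configured slope times
#' `(1 + Normal(0, lot_slope_rsd))`; responses at the calibration levels
#' are `(lot_slope * c + intercept)` times mean-1 lognormal noise with CV
#' `config$meas_cv`.
#'
#' @param config a [synthetic_config()].
#' @param n_lots,n_days design size.
#' @param analytes analyte identifiers to generate.
#' @return `data.frame` of calibration observations: `analyte`,
#'   `nominal_conc`, `response_ratio`, `day`, `lot`, `replicate`.
#' @export
generate_calibration_run <- function(config, n_lots = 1L, n_days = 1L,
                                     analytes = analyte_ids()) {
  stopifnot(inherits(config, "synthetic_config"), n_lots >= 1L,
            n_days >= 1L)
  stage_seed(config, 2L)
  levels <- config$cal_levels
  out <- list()
  for (an in analytes) {
    for (lot in seq_len(n_lots)) {
      lot_slope <- config$cal_slope[[an]] *
        (1 + rnorm(1, 0, config$lot_slope_rsd))
      for (day in seq_len(n_days)) {
        resp <- (lot_slope * levels + config$cal_intercept[[an]]) *
          ln_noise(length(levels), config$meas_cv)
        out[[length(out) + 1L]] <- data.frame(
          analyte = an, nominal_conc = levels,
          response_ratio = pmax(resp, 0), day = day,
          lot = sprintf("lot%02d", lot), replicate = 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Generate QC found-concentration tables
#'
#' Found concentrations are `nominal * (1 + level_bias) * noise` with mean-1
#' lognormal noise at CV `config$meas_cv`.
#'
#' @param config a [synthetic_config()].
#' @param levels nominal QC levels, ug/mL (within the calibration range).
#' @param n_reps replicates per day.
#' @param n_days validation days.
#' @param level_bias per-level proportional bias (scalar or one value per
#'   level), e.g. `0.037` for +3.7%.
#' @param analytes analyte identifiers to generate.
#' @return `data.frame` with `analyte`, `level`, `day`, `replicate`,
#'   `found`.
#' @export
generate_qc_run <- function(config, levels = c(0.3, 3, 15), n_reps = 5L,
                            n_days = 3L, level_bias = 0,
                            analytes = analyte_ids()) {
  stopifnot(inherits(config, "synthetic_config"), n_reps >= 1L,
            n_days >= 1L)
  if (any(levels < min(config$cal_levels) |
            levels > max(config$cal_levels))) {
    stop("QC levels must lie within the calibration range", call. = FALSE)
  }
  stage_seed(config, 3L)
  bias <- rep_len(level_bias, length(levels))
  out <- list()
  for (an in analytes) {
    for (li in seq_along(levels)) {
      for (day in seq_len(n_days)) {
        found <- levels[li] * (1 + bias[li]) *
          ln_noise(n_reps, config$meas_cv)
        out[[length(out) + 1L]] <- data.frame(
          analyte = an, level = levels[li], day = day,
          replicate = seq_len(n_reps), found = found,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
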