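# Pipeline orchestration: simulate -> calibrate/validate -> compare -> mpr,
# writing one CSV per stage output plus a human-readable summary. All
# stages are pure functions of (input files, config, seed): identical
# inputs and seed give identical outputs.

write_stage_csv <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

#' Run the full DBS TDM pipeline
#'
#' Executes the requested stages and writes their tabular outputs to
#' `out_dir`:
#' \describe{
#'   \item{simulate}{`cohort.csv`, `paired.csv`, `calibration_runs.csv`,
#'     `qc_runs.csv`, `manifest.json` (config + seed).}
#'   \item{validate}{`calibration.csv` (per analyte/lot/day fits),
#'     `qc_stats.csv`, `effects.csv` (matrix-effect slope RSD verdicts).}
#'   \item{compare}{`deming.csv`, `bland_altman.csv`,
#'     `calculated_plasma.csv`, `partition_fit.csv`.}
#'   \item{mpr}{`mpr_table.csv`, `flags.csv`.}
#' }
#' When `simulate` is not among the stages, the later stages read their
#' inputs from the paths given; at least one stage input must be present.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param stages character subset of
#'   `c("simulate", "validate", "compare", "mpr")`.
#' @param syn_config a [synthetic_config()] for the simulate stage;
#'   defaults to `synthetic_config(seed = config$seed)`.
#' @param paired_path,trough_path,calibration_path,qc_path CSV inputs for
#'   the non-simulated case.
#' @param k `"fit"` or fixed numeric, forwarded to [compare_dbs_plasma()]
#'   for the parent; the metabolite comparison always uses its own setting
#'   via `k_metabolite`.
#' @param k_metabolite `"fit"` or fixed numeric for the metabolite
#'   (default 0: glucuronides are excluded from blood cells).
#' @return invisibly, a list with the per-stage R objects and the paths
#'   written.
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         stages = c("simulate", "validate", "compare",
                                    "mpr"),
                         syn_config = NULL,
                         paired_path = NULL, trough_path = NULL,
                         calibration_path = NULL, qc_path = NULL,
                         k = "fit", k_metabolite = 0) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, c("simulate", "validate", "compare", "mpr"),
                      several.ok = TRUE)
  if (!"simulate" %in% stages && is.null(paired_path) &&
        is.null(trough_path) && is.null(calibration_path) &&
        is.null(qc_path)) {
    stop("usage error: no stage inputs given and 'simulate' not requested",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  paths <- character(0)

  paired <- NULL
  trough <- NULL
  cal_obs <- NULL
  qc_found <- NULL

  if ("simulate" %in% stages) {
    if (is.null(syn_config)) syn_config <- synthetic_config(seed = config$seed)
    cohort <- generate_cohort(syn_config)
    paired <- generate_paired(cohort, syn_config)
    cal_obs <- generate_calibration_run(syn_config, n_lots = 5L,
                                        n_days = 3L)
    qc_found <- generate_qc_run(syn_config)
    trough <- data.frame(subject_id = cohort$subject_id,
                         dose = cohort$dose,
                         parent_conc = paired$c_b[paired$analyte == "PARENT" &
                                                    paired$timepoint == "TROUGH"],
                         metabolite_conc = paired$c_b[paired$analyte == "METABOLITE" &
                                                        paired$timepoint == "TROUGH"],
                         stringsAsFactors = FALSE)
    paths <- c(paths,
               write_stage_csv(cohort, out_dir, "cohort.csv"),
               write_stage_csv(paired, out_dir, "paired.csv"),
               write_stage_csv(cal_obs, out_dir, "calibration_runs.csv"),
               write_stage_csv(qc_found, out_dir, "qc_runs.csv"),
               write_stage_csv(trough, out_dir, "trough_table.csv"))
    manifest <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(
      list(seed = syn_config$seed,
           config = unclass(syn_config)[!vapply(unclass(syn_config),
                                                is.null, logical(1))]),
      manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, manifest)
    results$cohort <- cohort
  } else {
    if (!is.null(paired_path)) paired <- read_paired_table(paired_path)
    if (!is.null(trough_path)) trough <- read_trough_table(trough_path)
    if (!is.null(calibration_path)) {
      cal_obs <- read.csv(calibration_path, stringsAsFactors = FALSE)
    }
    if (!is.null(qc_path)) qc_found <- read.csv(qc_path,
                                                stringsAsFactors = FALSE)
  }
  results$paired <- paired

  if ("validate" %in% stages && !is.null(cal_obs)) {
    combos <- unique(cal_obs[, c("analyte", "lot", "day")])
    fits <- lapply(seq_len(nrow(combos)), function(i) {
      sub <- cal_obs[cal_obs$analyte == combos$analyte[i] &
                       cal_obs$lot == combos$lot[i] &
                       cal_obs$day == combos$day[i], ]
      fit_calibration(sub)
    })
    cal_df <- data.frame(analyte = combos$analyte, lot = combos$lot,
                         day = combos$day,
                         slope = vapply(fits, `[[`, numeric(1), "slope"),
                         intercept = vapply(fits, `[[`, numeric(1),
                                            "intercept"),
                         r2 = vapply(fits, `[[`, numeric(1), "r2"),
                         stringsAsFactors = FALSE)
    paths <- c(paths, write_stage_csv(cal_df, out_dir, "calibration.csv"))
    effects <- do.call(rbind, lapply(unique(cal_df$analyte), function(an) {
      sl <- cal_df$slope[cal_df$analyte == an]
      me <- matrix_effect_slopes(sl,
                                 threshold = config$matrix_slope_rsd_pct)
      data.frame(analyte = an, factor = "MATRIX", rsd_pct = me$rsd_pct,
                 threshold = me$threshold, pass = me$pass,
                 stringsAsFactors = FALSE)
    }))
    paths <- c(paths, write_stage_csv(effects, out_dir, "effects.csv"))
    results$calibration <- cal_df
    results$effects <- effects
    if (!is.null(qc_found)) {
      qc <- qc_stats(qc_found)
      paths <- c(paths, write_stage_csv(qc, out_dir, "qc_stats.csv"))
      results$qc_stats <- qc
    }
  }

  if ("compare" %in% stages && !is.null(paired)) {
    comparisons <- list(
      PARENT = compare_dbs_plasma(paired, "PARENT", k = k),
      METABOLITE = compare_dbs_plasma(paired, "METABOLITE",
                                      k = k_metabolite))
    deming_df <- do.call(rbind, lapply(names(comparisons), function(an) {
      cp <- comparisons[[an]]
      do.call(rbind, lapply(c("deming_raw", "deming_calc"), function(which) {
        d <- cp[[which]]
        data.frame(analyte = an, comparison = sub("deming_", "", which),
                   slope = d$slope, slope_lo = d$slope_ci[1],
                   slope_hi = d$slope_ci[2], intercept = d$intercept,
                   intercept_lo = d$intercept_ci[1],
                   intercept_hi = d$intercept_ci[2], n = d$n,
                   stringsAsFactors = FALSE)
      }))
    }))
    ba_df <- do.call(rbind, lapply(names(comparisons), function(an) {
      cp <- comparisons[[an]]
      do.call(rbind, lapply(c("ba_raw", "ba_calc"), function(which) {
        b <- cp[[which]]
        data.frame(analyte = an, comparison = sub("ba_", "", which),
                   mean_diff = b$mean_diff, sd_diff = b$sd_diff,
                   loa_low = b$loa_low, loa_high = b$loa_high,
                   ci_lo = b$ci_mean_diff[1], ci_hi = b$ci_mean_diff[2],
                   n = b$n, stringsAsFactors = FALSE)
      }))
    }))
    calc_df <- do.call(rbind, lapply(names(comparisons), function(an) {
      comparisons[[an]]$calculated
    }))
    part_df <- do.call(rbind, lapply(names(comparisons), function(an) {
      p <- comparisons[[an]]$partition
      if (inherits(p, "partition_fit")) {
        data.frame(analyte = an, k_bcpl = p$k_bcpl, source = "fit",
                   ci_low = p$ci_low, ci_high = p$ci_high, n = p$n,
                   sse = p$sse, stringsAsFactors = FALSE)
      } else {
        data.frame(analyte = an, k_bcpl = p, source = "fixed",
                   ci_low = NA_real_, ci_high = NA_real_, n = NA_integer_,
                   sse = NA_real_, stringsAsFactors = FALSE)
      }
    }))
    paths <- c(paths,
               write_stage_csv(deming_df, out_dir, "deming.csv"),
               write_stage_csv(ba_df, out_dir, "bland_altman.csv"),
               write_stage_csv(calc_df, out_dir, "calculated_plasma.csv"),
               write_stage_csv(part_df, out_dir, "partition_fit.csv"))
    results$comparisons <- comparisons
  }

  if ("mpr" %in% stages && !is.null(trough)) {
    mpr <- summarize_cohort(trough)
    mpr_df <- mpr$table
    mpr_df$mpr <- round(mpr_df$mpr, 3)
    flags <- mpr$table[, c("subject_id", "mpr", "outlier")]
    paths <- c(paths,
               write_stage_csv(mpr_df, out_dir, "mpr_table.csv"),
               write_stage_csv(flags, out_dir, "flags.csv"))
    results$mpr <- mpr
  }

  summary_path <- file.path(out_dir, "summary.txt")
  summary_lines <- utils::capture.output({
  cat("DBS TDM pipeline summary\n")
  cat("stages:", paste(stages, collapse = ", "), "  seed:", config$seed,
      "\n\n")
  if (!is.null(results$calibration)) {
    cat("calibration fits:", nrow(results$calibration), "curves, median r2",
        sprintf("%.4f", median(results$calibration$r2)), "\n")
  }
  if (!is.null(results$effects)) {
    for (i in seq_len(nrow(results$effects))) {
      cat(sprintf("matrix effect %s: slope RSD %.2f%% (< %g%%: %s)\n",
                  results$effects$analyte[i], results$effects$rsd_pct[i],
                  results$effects$threshold[i],
                  ifelse(results$effects$pass[i], "pass", "FAIL")))
    }
  }
  if (!is.null(results$comparisons)) {
    for (an in names(results$comparisons)) print(results$comparisons[[an]])
  }
  if (!is.null(results$mpr)) print(results$mpr)
  })
  writeLines(summary_lines, summary_path)
  paths <- c(paths, summary_path)

  invisible(c(results, list(paths = paths, out_dir = out_dir)))
}
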