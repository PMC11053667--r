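# Calibration fitting and the bioanalytical validation statistic suite:
# LLOQ criteria, accuracy/precision, recovery, relative matrix effect,
# haematocrit effect, spot-volume effect, stability.

cv_pct <- function(x) 100 * sd(x) / mean(x)
bias_pct <- function(found, nominal) 100 * (mean(found) - nominal) / nominal

#' Fit a calibration curve by linear regression
#'
#' Ordinary (non-weighted) least squares of the analyte/IS response ratio on
#' nominal concentration, following standard bioanalytical practice for this
#' assay. A `1/x^2` weighted fit is available behind `weighting` for assays
#' with strongly proportional error, default off. Blanks (nominal 0) are
#' excluded from the fit. At least 6 distinct non-zero levels are required
#' (guideline minimum).
#'
#' @param obs `data.frame` of calibration observations with columns
#'   `nominal_conc` (ug/mL) and `response_ratio` (analyte/IS peak-area
#'   ratio); optional `analyte`, `day`, `lot` are carried through when
#'   unique.
#' @param weighting `"none"` (default) or `"inv_conc_sq"` (weights
#'   `1/nominal^2`).
#' @return an object of class `calibration_curve`: `slope` (response ratio
#'   per ug/mL), `intercept`, `r2`, `n_levels`, `n_obs`, and `residuals`, a
#'   per-level table of mean back-calculated concentration and bias %.
#' @examples
#' lv <- c(0.1, 0.25, 0.5, 0.75, 1, 5, 7.5, 10, 12.5, 17.5, 20)
#' fit_calibration(data.frame(nominal_conc = lv,
#'                            response_ratio = 0.1683 * lv - 0.0012))
#' @export
fit_calibration <- function(obs, weighting = c("none", "inv_conc_sq")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("nominal_conc", "response_ratio") %in% names(obs)))
  if (any(obs$response_ratio < 0, na.rm = TRUE)) {
    stop("response_ratio must be non-negative", call. = FALSE)
  }
  std <- obs[obs$nominal_conc > 0, ]
  levels_used <- sort(unique(std$nominal_conc))
  if (length(levels_used) < 6L) {
    stop("calibration design error: need >= 6 distinct non-zero levels, got ",
         length(levels_used), call. = FALSE)
  }
  w <- if (weighting == "inv_conc_sq") 1 / std$nominal_conc^2 else NULL
  fit <- lm(response_ratio ~ nominal_conc, data = std, weights = w)
  slope <- unname(coef(fit)["nominal_conc"])
  intercept <- unname(coef(fit)["(Intercept)"])
  if (slope <= 0) {
    stop("calibration design error: non-positive slope (", signif(slope, 4),
         ")", call. = FALSE)
  }
  wr <- if (is.null(w)) rep(1, nrow(std)) else w
  fitted_vals <- intercept + slope * std$nominal_conc
  ss_res <- sum(wr * (std$response_ratio - fitted_vals)^2)
  ybar <- sum(wr * std$response_ratio) / sum(wr)
  ss_tot <- sum(wr * (std$response_ratio - ybar)^2)
  r2 <- 1 - ss_res / ss_tot
  back <- (std$response_ratio - intercept) / slope
  res <- do.call(rbind, lapply(levels_used, function(lv) {
    b <- back[std$nominal_conc == lv]
    data.frame(nominal_conc = lv, mean_back_calc = mean(b),
               bias_pct = 100 * (mean(b) - lv) / lv)
  }))
  meta <- lapply(c("analyte", "day", "lot"), function(col) {
    if (col %in% names(obs) && length(unique(obs[[col]])) == 1L) {
      obs[[col]][1]
    } else NA
  })
  structure(list(analyte = meta[[1]], day = meta[[2]], lot = meta[[3]],
                 slope = slope, intercept = intercept, r2 = r2,
                 n_levels = length(levels_used), n_obs = nrow(std),
                 weighting = weighting, residuals = res),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, digits = 4, ...) {
  cat("Calibration curve (", x$weighting, " linear regression)\n", sep = "")
  if (!is.na(x$analyte)) cat("  analyte:", x$analyte, "\n")
  cat(sprintf("  slope %.*g  intercept %.*g  r2 %.4f  (%d levels, %d obs)\n",
              digits, x$slope, digits, x$intercept, x$r2, x$n_levels,
              x$n_obs))
  invisible(x)
}

#' Back-calculate a concentration from a response ratio
#'
#' Inverse of the calibration line: `(response_ratio - intercept) / slope`.
#' Results below zero (sub-blank responses) are returned as is, not clipped;
#' use [flag_blq()] to mark values below the LLOQ.
#'
#' @param curve a `calibration_curve`.
#' @param response_ratio numeric vector of analyte/IS ratios.
#' @return concentrations, ug/mL.
#' @export
back_calculate <- function(curve, response_ratio) {
  stopifnot(inherits(curve, "calibration_curve"), curve$slope > 0)
  (response_ratio - curve$intercept) / curve$slope
}

#' Flag concentrations below the lower limit of quantification
#'
#' @param conc concentrations, ug/mL.
#' @param lloq lower limit of quantification, ug/mL.
#' @return logical vector, `TRUE` where `conc < lloq`. BLQ values are
#'   retained in validation computations but excluded from patient reports.
#' @export
flag_blq <- function(conc, lloq) conc < lloq

#' Check the LLOQ acceptance criteria
#'
#' The LLOQ passes when replicate precision (CV) and accuracy (|bias|) do
#' not exceed `cv_limit`/`bias_limit` (20% by convention) and the analyte
#' signal is at least `signal_ratio_min`-fold the blank signal. A zero blank
#' gives an infinite signal ratio, which passes the fold rule.
#'
#' @param replicates found concentrations at the lowest level, ug/mL
#'   (n >= 3).
#' @param nominal nominal LLOQ concentration, ug/mL.
#' @param blank_signal,lloq_signal raw signal responses of blank and LLOQ
#'   samples.
#' @param cv_limit,bias_limit,signal_ratio_min acceptance thresholds.
#' @return list with `cv_pct`, `bias_pct`, `signal_ratio`, `pass`, and the
#'   per-rule verdicts.
#' @export
lloq_check <- function(replicates, nominal, blank_signal, lloq_signal,
                       cv_limit = 20, bias_limit = 20,
                       signal_ratio_min = 5) {
  if (length(replicates) < 3L) {
    stop("LLOQ check needs >= 3 replicates", call. = FALSE)
  }
  if (nominal <= 0) stop("nominal must be > 0", call. = FALSE)
  cv <- cv_pct(replicates)
  bias <- bias_pct(replicates, nominal)
  ratio <- if (blank_signal == 0) Inf else lloq_signal / blank_signal
  pass_cv <- cv <= cv_limit
  pass_bias <- abs(bias) <= bias_limit
  pass_signal <- ratio >= signal_ratio_min
  list(cv_pct = cv, bias_pct = bias, signal_ratio = ratio,
       pass_cv = pass_cv, pass_bias = pass_bias, pass_signal = pass_signal,
       pass = pass_cv && pass_bias && pass_signal)
}

#' Intra- and inter-day accuracy and precision of QC samples
#'
#' For each (analyte,) level: intra-day statistics per day (n >= 2
#' replicates), and inter-day statistics pooling all replicate values
#' across days (not averaging daily means). Accuracy is
#' `bias% = 100 * (mean_found - nominal) / nominal`; precision is
#' `CV% = 100 * sd / mean_found` with the sample (n - 1) standard
#' deviation.
#'
#' @param found `data.frame` with columns `level` (nominal concentration,
#'   ug/mL), `day`, `found` (ug/mL); optional `analyte`.
#' @return `data.frame` of class `qc_stats` with columns `analyte`,
#'   `level`, `scope` (`INTRA_DAY`/`INTER_DAY`), `day` (NA for inter-day),
#'   `n`, `mean_found`, `cv_pct`, `bias_pct`.
#' @examples
#' found <- data.frame(level = 3, day = rep(1:3, each = 5),
#'                     found = 3 * rlnorm(15, -0.0013, 0.05))
#' qc_stats(found)
#' @export
qc_stats <- function(found) {
  stopifnot(all(c("level", "day", "found") %in% names(found)))
  if (any(found$level <= 0)) {
    stop("nominal level must be > 0", call. = FALSE)
  }
  if (!"analyte" %in% names(found)) found$analyte <- NA_character_
  akey <- ifelse(is.na(found$analyte), "", as.character(found$analyte))
  out <- list()
  for (an in unique(akey)) {
    fa <- found[akey == an, ]
    an <- if (an == "") NA_character_ else an
    for (lv in sort(unique(fa$level))) {
      fl <- fa[fa$level == lv, ]
      for (d in sort(unique(fl$day))) {
        v <- fl$found[fl$day == d]
        if (length(v) >= 2L) {
          out[[length(out) + 1L]] <- data.frame(
            analyte = an, level = lv, scope = "INTRA_DAY", day = d,
            n = length(v), mean_found = mean(v), cv_pct = cv_pct(v),
            bias_pct = bias_pct(v, lv), stringsAsFactors = FALSE)
        }
      }
      if (length(unique(fl$day)) >= 2L) {
        v <- fl$found
        out[[length(out) + 1L]] <- data.frame(
          analyte = an, level = lv, scope = "INTER_DAY", day = NA,
          n = length(v), mean_found = mean(v), cv_pct = cv_pct(v),
          bias_pct = bias_pct(v, lv), stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("qc_stats", "data.frame")
  res
}

#' Relative matrix effect via calibration-slope dispersion
#'
#' The relative matrix effect is assessed from calibration curves prepared
#' in blood from different donors (matrix lots): an RSD of the slopes below
#' the threshold (4% by convention) indicates the method is free from
#' significant relative matrix effects.
#'
#' @param slopes numeric vector of calibration slopes, or a list of
#'   `calibration_curve` objects (>= 3 lots).
#' @param threshold RSD ceiling, percent.
#' @return list with `rsd_pct`, `n_lots`, `threshold`, `pass`.
#' @export
matrix_effect_slopes <- function(slopes, threshold = 4) {
  if (is.list(slopes)) {
    slopes <- vapply(slopes, function(s) {
      if (inherits(s, "calibration_curve")) s$slope else as.numeric(s)
    }, numeric(1))
  }
  if (length(slopes) < 3L) {
    stop("matrix-effect assessment needs slopes from >= 3 lots",
         call. = FALSE)
  }
  if (mean(slopes) <= 0) stop("mean slope must be > 0", call. = FALSE)
  rsd <- cv_pct(slopes)
  list(rsd_pct = rsd, n_lots = length(slopes), threshold = threshold,
       pass = rsd < threshold)
}

#' Extraction recovery
#'
#' Recovery compares responses of (A) extracted spiked DBS samples with (B)
#' blank DBS extracts spiked post-extraction at the same level:
#' `100 * A / B` per replicate pair, with the mean and CV across replicates.
#'
#' @param extracted_response response(s) of extracted spiked samples (A).
#' @param post_extraction_spiked_response matched post-extraction spiked
#'   responses (B), all > 0.
#' @return list with `recovery_pct` (per pair), `mean_pct`, `cv_pct` (NA for
#'   a single pair).
#' @export
recovery <- function(extracted_response, post_extraction_spiked_response) {
  a <- extracted_response
  b <- post_extraction_spiked_response
  if (length(a) != length(b)) stop("A and B must have equal length",
                                   call. = FALSE)
  if (any(b <= 0)) stop("post-extraction spiked response must be > 0",
                        call. = FALSE)
  if (any(a < 0)) stop("extracted response must be >= 0", call. = FALSE)
  rec <- 100 * a / b
  list(recovery_pct = rec, mean_pct = mean(rec),
       cv_pct = if (length(rec) > 1L) cv_pct(rec) else NA_real_)
}

effect_table <- function(df) {
  class(df) <- c("effect_table", "data.frame")
  df
}

#' Haematocrit effect on quantification accuracy
#'
#' Samples prepared at several haematocrit levels and QC concentrations are
#' quantified against a calibration at the reference haematocrit; bias% and
#' CV% per (haematocrit, level) cell are compared against the acceptance
#' threshold (+/-15% by convention).
#'
#' @param found `data.frame` with columns `hct` (fraction or percent),
#'   `level` (nominal, ug/mL), `found` (ug/mL), replicate rows per cell.
#' @param threshold acceptance bound, percent, applied to |bias| and CV.
#' @return `effect_table` data frame with one row per cell: `factor`
#'   (`"HCT"`), `condition` (haematocrit), `level`, `n`, `bias_pct`,
#'   `cv_pct`, `threshold`, `pass`.
#' @export
hct_effect <- function(found, threshold = 15) {
  stopifnot(all(c("hct", "level", "found") %in% names(found)))
  found$hct <- normalize_hct(found$hct)
  if (length(unique(found$hct)) < 2L) {
    stop("haematocrit effect needs >= 2 Hct levels", call. = FALSE)
  }
  cells <- unique(found[, c("hct", "level")])
  cells <- cells[order(cells$hct, cells$level), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    v <- found$found[found$hct == cells$hct[i] &
                       found$level == cells$level[i]]
    b <- bias_pct(v, cells$level[i])
    cv <- if (length(v) > 1L) cv_pct(v) else NA_real_
    data.frame(factor = "HCT", condition = cells$hct[i],
               level = cells$level[i], n = length(v), bias_pct = b,
               cv_pct = cv, threshold = threshold,
               pass = abs(b) <= threshold &&
                 (is.na(cv) || cv <= threshold),
               stringsAsFactors = FALSE)
  })
  effect_table(do.call(rbind, rows))
}

#' Blood-spot volume effect
#'
#' Analyte/IS response ratios measured from spots of different volumes are
#' compared to the reference volume; the overall CV% across per-volume mean
#' ratios quantifies the volume effect.
#'
#' @param ratios `data.frame` with columns `volume` (uL) and `ratio`
#'   (analyte/IS), replicate rows per volume.
#' @param reference_volume uL; must be among the tested volumes.
#' @return list with `per_volume` (`effect_table`: mean ratio and percent of
#'   reference per volume) and `cv_pct` across the per-volume means.
#' @export
volume_effect <- function(ratios, reference_volume = 10) {
  stopifnot(all(c("volume", "ratio") %in% names(ratios)))
  vols <- sort(unique(ratios$volume))
  if (!reference_volume %in% vols) {
    stop("volume-effect design error: reference volume ", reference_volume,
         " uL not among tested volumes", call. = FALSE)
  }
  if (length(vols) < 2L) {
    stop("volume-effect design error: need >= 2 spot volumes",
         call. = FALSE)
  }
  means <- vapply(vols, function(v) mean(ratios$ratio[ratios$volume == v]),
                  numeric(1))
  ref <- means[vols == reference_volume]
  per_volume <- effect_table(data.frame(
    factor = "VOLUME", condition = vols, level = NA_real_,
    n = as.integer(table(factor(ratios$volume, levels = vols))),
    mean_ratio = means, pct_of_reference = 100 * means / ref,
    stringsAsFactors = FALSE))
  list(per_volume = per_volume, cv_pct = cv_pct(means),
       reference_volume = reference_volume)
}

#' Storage stability as percent of fresh samples
#'
#' Stored samples are compared to freshly prepared samples at matched QC
#' levels: `%remaining = 100 * stored / fresh` per condition x level, with a
#' pass verdict when the ratio lies within `100 +/- threshold` percent.
#'
#' @param stored `data.frame` with columns `condition` (e.g. "28 days at
#'   25 C"), `level` (ug/mL), `found` (ug/mL).
#' @param fresh `data.frame` with columns `level`, `found` for freshly
#'   spiked samples.
#' @param threshold acceptance half-width, percent.
#' @return `effect_table` with one row per condition x level: `pct_remaining`
#'   and `pass`.
#' @export
stability_ratios <- function(stored, fresh, threshold = 15) {
  stopifnot(all(c("condition", "level", "found") %in% names(stored)),
            all(c("level", "found") %in% names(fresh)))
  cells <- unique(stored[, c("condition", "level")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    lv <- cells$level[i]
    f <- fresh$found[fresh$level == lv]
    if (length(f) == 0L) {
      stop("no fresh samples at level ", lv, call. = FALSE)
    }
    fm <- mean(f)
    if (fm == 0) stop("fresh mean concentration is 0 at level ", lv,
                      call. = FALSE)
    sm <- mean(stored$found[stored$condition == cells$condition[i] &
                              stored$level == lv])
    pct <- 100 * sm / fm
    data.frame(factor = "STABILITY", condition = cells$condition[i],
               level = lv, pct_remaining = pct, threshold = threshold,
               pass = abs(pct - 100) <= threshold,
               stringsAsFactors = FALSE)
  })
  effect_table(do.call(rbind, rows))
}
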