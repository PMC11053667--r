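# Typed tabular I/O and run configuration.
#
# Concentrations are ug/mL throughout; haematocrit is a fraction in (0,1)
# internally. Values supplied as percent (in (1, 100]) are divided by 100 on
# input. Missing c_pl / hct are empty CSV cells, never 0.

.analytes <- c(PARENT = "LTG", METABOLITE = "LTG-N2-GLU")
.timepoints <- c("TROUGH", "PEAK")

#' Analyte identifiers and display labels
#'
#' The study quantifies exactly two analytes: the parent drug lamotrigine
#' ("LTG") and its main metabolite lamotrigine-N2-glucuronide ("LTG-N2-GLU").
#'
#' @return `analyte_ids()` returns `c("PARENT", "METABOLITE")`;
#'   `analyte_label()` maps identifiers to display labels.
#' @examples
#' analyte_ids()
#' analyte_label("PARENT")
#' @export
analyte_ids <- function() names(.analytes)

#' @rdname analyte_ids
#' @param analyte character vector of analyte identifiers or labels.
#' @export
analyte_label <- function(analyte) {
  unname(.analytes[as_analyte(analyte)])
}

#' Canonicalize analyte codes
#'
#' Accepts either the identifiers `PARENT`/`METABOLITE` or the display labels
#' `LTG`/`LTG-N2-GLU` (case-insensitive for identifiers) and returns the
#' canonical identifier.
#'
#' @param x character vector.
#' @return character vector of `"PARENT"`/`"METABOLITE"`.
#' @export
as_analyte <- function(x) {
  x <- as.character(x)
  up <- toupper(x)
  out <- ifelse(up %in% names(.analytes), up,
                names(.analytes)[match(x, .analytes)])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown analyte code(s): ", paste(bad, collapse = ", "),
         " (expected PARENT/METABOLITE or LTG/LTG-N2-GLU)", call. = FALSE)
  }
  out
}

#' Normalize haematocrit to a fraction
#'
#' Haematocrit is stored as a volume fraction in (0, 1). Values in
#' \[15, 100\] are interpreted as percent and divided by 100 (clinical
#' sources commonly report "Hct %", and no human haematocrit is below
#' ~15%). Values in (1, 15) are ambiguous — too large for a fraction, too
#' small for a percent — and are passed through unchanged so that
#' validation rejects them. `NA` passes through.
#'
#' @param hct numeric vector.
#' @return numeric vector of fractions.
#' @examples
#' normalize_hct(c(0.45, 45, NA))
#' @export
normalize_hct <- function(hct) {
  ifelse(!is.na(hct) & hct >= 15 & hct <= 100, hct / 100, hct)
}

# Validate a paired-measurement data frame in place; `where` labels error
# messages with the data origin (e.g. a file path). Returns the cleaned frame.
validate_paired <- function(df, where = "paired table") {
  req <- c("subject_id", "analyte", "timepoint", "c_b", "c_pl", "hct")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop(where, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  df$analyte <- if (nrow(df)) as_analyte(df$analyte) else character(0)
  df$timepoint <- toupper(as.character(df$timepoint))
  bad_tp <- which(!df$timepoint %in% .timepoints)
  if (length(bad_tp) > 0L) {
    stop(where, ": invalid timepoint at row(s) ",
         paste(bad_tp, collapse = ", "), " (expected TROUGH or PEAK)",
         call. = FALSE)
  }
  for (col in c("c_b", "c_pl", "hct")) df[[col]] <- as.numeric(df[[col]])
  bad <- which(is.na(df$c_b) | df$c_b < 0)
  if (length(bad) > 0L) {
    stop(where, ": c_b must be a non-negative number at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.na(df$c_pl) & df$c_pl < 0)
  if (length(bad) > 0L) {
    stop(where, ": negative c_pl at row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df$hct <- normalize_hct(df$hct)
  bad <- which(!is.na(df$hct) & (df$hct <= 0 | df$hct >= 1))
  if (length(bad) > 0L) {
    stop(where, ": hct outside (0, 1) at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df
}

#' Construct a paired-measurement table
#'
#' One record per subject x analyte x timepoint, holding the whole-blood
#' (DBS) concentration and, when available, the paired plasma concentration
#' and the subject's haematocrit.
#'
#' @param subject_id character vector.
#' @param analyte `"PARENT"`/`"METABOLITE"` (labels also accepted).
#' @param timepoint `"TROUGH"` or `"PEAK"`.
#' @param c_b whole-blood (DBS) concentration, ug/mL.
#' @param c_pl plasma concentration, ug/mL; `NA` when not measured.
#' @param hct haematocrit fraction in (0, 1); percent values in (1, 100] are
#'   divided by 100. `NA` when unknown.
#' @return a validated `data.frame` with those six columns.
#' @export
paired_measurements <- function(subject_id, analyte, timepoint, c_b,
                                c_pl = NA_real_, hct = NA_real_) {
  df <- data.frame(subject_id = as.character(subject_id),
                   analyte = analyte, timepoint = timepoint,
                   c_b = c_b, c_pl = c_pl, hct = hct,
                   stringsAsFactors = FALSE)
  validate_paired(df, where = "paired_measurements()")
}

#' Read and write paired DBS/plasma measurement tables
#'
#' CSV dialect: comma-separated, UTF-8, "." decimal separator, mandatory
#' header with columns `subject_id, analyte, timepoint, c_b, c_pl, hct`
#' (the last two may be empty). Writing then reading a table is the identity
#' on all fields; missing values are written as empty cells.
#'
#' @param path CSV file path.
#' @return `read_paired_table()` returns the validated `data.frame`, row
#'   order preserved.
#' @export
read_paired_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = NA)
  validate_paired(df, where = path)
}

#' @rdname read_paired_table
#' @param df a paired-measurement `data.frame`.
#' @export
write_paired_table <- function(df, path) {
  df <- validate_paired(df, where = "write_paired_table()")
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a wide trough-concentration table
#'
#' Trough tables record one row per subject with the daily dose and the
#' trough DBS concentrations of both analytes, the format used for
#' metabolite-to-parent-ratio screening. Required columns:
#' `subject_id, dose, parent_conc, metabolite_conc` (dose mg/day,
#' concentrations ug/mL).
#'
#' @param path CSV file path.
#' @return `data.frame` with the four columns, row order preserved.
#' @export
read_trough_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "dose", "parent_conc", "metabolite_conc")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop(path, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  for (col in c("dose", "parent_conc", "metabolite_conc")) {
    df[[col]] <- as.numeric(df[[col]])
    bad <- which(is.na(df[[col]]) | df[[col]] < 0)
    if (length(bad) > 0L) {
      stop(path, ": ", col, " must be a non-negative number at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  df
}

#' Expand a wide trough table into long paired-measurement records
#'
#' Each subject row becomes two records (one per analyte), timepoint
#' `TROUGH`, with plasma concentration and haematocrit missing.
#'
#' @param trough `data.frame` as returned by [read_trough_table()].
#' @return paired-measurement `data.frame` with `2 * nrow(trough)` records.
#' @export
trough_to_paired <- function(trough) {
  long <- rbind(
    data.frame(subject_id = trough$subject_id, analyte = "PARENT",
               timepoint = "TROUGH", c_b = trough$parent_conc,
               c_pl = NA_real_, hct = NA_real_, stringsAsFactors = FALSE),
    data.frame(subject_id = trough$subject_id, analyte = "METABOLITE",
               timepoint = "TROUGH", c_b = trough$metabolite_conc,
               c_pl = NA_real_, hct = NA_real_, stringsAsFactors = FALSE))
  validate_paired(long, where = "trough_to_paired()")
}

#' Built-in nine-patient trough cohort
#'
#' Steady-state trough DBS concentrations of lamotrigine and its
#' N2-glucuronide in nine adult patients on stable oral lamotrigine therapy
#' (100-400 mg/day), sampled immediately before the morning dose. This is
#' the worked example used throughout the package documentation; the same
#' table ships as a CSV in `inst/extdata/ltg_trough_cohort.csv`.
#'
#' @return `data.frame` with columns `subject_id`, `dose` (mg/day),
#'   `parent_conc`, `metabolite_conc` (ug/mL).
#' @examples
#' summarize_cohort(ltg_trough_cohort())
#' @export
ltg_trough_cohort <- function() {
  data.frame(
    subject_id = as.character(1:9),
    dose = c(100, 200, 250, 400, 100, 300, 100, 250, 400),
    parent_conc = c(4.61, 3.14, 6.42, 3.50, 1.83, 6.09, 1.84, 3.48, 9.39),
    metabolite_conc = c(0.37, 1.41, 1.63, 2.14, 0.60, 2.10, 0.31, 1.09, 3.22),
    stringsAsFactors = FALSE)
}

#' Run configuration for the TDM pipeline
#'
#' Bundles the assay design constants and acceptance thresholds used by the
#' validation and reporting stages. Defaults reflect the validated DBS assay:
#' 11 calibration levels spanning 0.1-20 ug/mL, LLOQ 0.1 ug/mL, QC levels
#' 0.3/3/15 ug/mL, +/-15% bias/CV acceptance (20% at the LLOQ), and a 4%
#' calibration-slope RSD ceiling for relative matrix effects.
#'
#' @param lloq lower limit of quantification, ug/mL; must equal the smallest
#'   calibration level.
#' @param cal_levels calibration standard concentrations, ug/mL.
#' @param qc_levels quality-control concentrations, ug/mL.
#' @param acceptance_bias_cv_pct bias/CV acceptance threshold, percent.
#' @param lloq_bias_cv_pct bias/CV acceptance threshold at the LLOQ, percent.
#' @param matrix_slope_rsd_pct relative matrix-effect slope RSD ceiling,
#'   percent.
#' @param seed integer seed forwarded to the synthetic generator.
#' @param ... unused; supplying an unknown key is an error.
#' @return an object of class `run_config`.
#' @export
run_config <- function(lloq = 0.1,
                       cal_levels = c(0.1, 0.25, 0.5, 0.75, 1, 5, 7.5,
                                      10, 12.5, 17.5, 20),
                       qc_levels = c(0.3, 3, 15),
                       acceptance_bias_cv_pct = 15,
                       lloq_bias_cv_pct = 20,
                       matrix_slope_rsd_pct = 4,
                       seed = 1L, ...) {
  extra <- list(...)
  if (length(extra) > 0L) {
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  }
  if (!isTRUE(all.equal(lloq, min(cal_levels)))) {
    stop("lloq must equal the smallest calibration level", call. = FALSE)
  }
  thresholds <- c(acceptance_bias_cv_pct, lloq_bias_cv_pct,
                  matrix_slope_rsd_pct)
  if (any(thresholds <= 0)) stop("thresholds must be > 0", call. = FALSE)
  structure(list(lloq = lloq, cal_levels = sort(cal_levels),
                 qc_levels = qc_levels,
                 acceptance_bias_cv_pct = acceptance_bias_cv_pct,
                 lloq_bias_cv_pct = lloq_bias_cv_pct,
                 matrix_slope_rsd_pct = matrix_slope_rsd_pct,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("TDM run configuration\n")
  cat("  calibration levels (ug/mL):", paste(x$cal_levels, collapse = ", "),
      "\n")
  cat("  LLOQ:", x$lloq, "ug/mL   QC levels:",
      paste(x$qc_levels, collapse = ", "), "ug/mL\n")
  cat("  acceptance bias/CV: +/-", x$acceptance_bias_cv_pct,
      "% (", x$lloq_bias_cv_pct, "% at LLOQ);  matrix slope RSD <",
      x$matrix_slope_rsd_pct, "%\n", sep = "")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
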