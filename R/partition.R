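# Blood <-> plasma conversion with haematocrit and blood-cell partitioning.
#
# Whole blood is a two-compartment mixture of plasma (volume fraction
# 1 - Hct) and blood cells (Hct). With K = c_BC / c_PL the cell-to-plasma
# partition coefficient, mass balance gives
#
#   c_B = c_PL * ((1 - Hct) + K * Hct)
#
# K = 0 (analyte excluded from cells, e.g. the glucuronide) reduces to the
# plain haematocrit correction c_PL = c_B / (1 - Hct); K = 1 makes blood and
# plasma concentrations identical at every haematocrit.

#' Convert between whole-blood (DBS) and plasma concentrations
#'
#' `plasma_from_blood()` computes `c_b / ((1 - hct) + k_bcpl * hct)`;
#' `blood_from_plasma()` is its exact inverse. With `k_bcpl = 0` this is the
#' plain haematocrit correction for an analyte confined to plasma.
#'
#' @param c_b whole-blood concentration, ug/mL (non-negative).
#' @param c_pl plasma concentration, ug/mL (non-negative).
#' @param hct haematocrit as a fraction; percent values in (1, 100] are
#'   divided by 100.
#' @param k_bcpl blood-cell-to-plasma partition coefficient (>= 0).
#' @return concentration vector, ug/mL.
#' @examples
#' plasma_from_blood(3.52, 0.45, 0)      # 6.4: glucuronide-type correction
#' plasma_from_blood(2.513, 0.45, 1.57)  # ~2.0: parent drug with K = 1.57
#' blood_from_plasma(2.0, 0.45, 1.57)
#' @export
plasma_from_blood <- function(c_b, hct, k_bcpl) {
  check_partition_args(c_b, hct, k_bcpl, what = "c_b")
  hct <- normalize_hct(hct)
  denom <- (1 - hct) + k_bcpl * hct
  if (any(denom <= 0, na.rm = TRUE)) {
    stop("partition denominator (1 - hct) + k * hct is not positive ",
         "(hct = 1 requires k > 0)", call. = FALSE)
  }
  c_b / denom
}

#' @rdname plasma_from_blood
#' @export
blood_from_plasma <- function(c_pl, hct, k_bcpl) {
  check_partition_args(c_pl, hct, k_bcpl, what = "c_pl")
  hct <- normalize_hct(hct)
  c_pl * ((1 - hct) + k_bcpl * hct)
}

check_partition_args <- function(conc, hct, k_bcpl, what) {
  if (any(conc < 0, na.rm = TRUE)) {
    stop(what, " must be non-negative", call. = FALSE)
  }
  if (any(k_bcpl < 0, na.rm = TRUE)) {
    stop("k_bcpl must be non-negative", call. = FALSE)
  }
  h <- normalize_hct(hct)
  if (any(h < 0 | h > 1, na.rm = TRUE)) {
    stop("hct must lie in [0, 1] (or (1, 100] as percent)", call. = FALSE)
  }
  invisible(NULL)
}

#' Estimate the blood-cell-to-plasma partition coefficient
#'
#' Fits the scalar partition coefficient K by nonlinear least squares on the
#' plasma scale: K minimizes `sum((c_pl - c_b / ((1 - hct) + K * hct))^2)`
#' over the paired records with complete blood, plasma and haematocrit
#' fields. The problem is one-dimensional, so a bracketed scalar minimizer
#' over `interval` is used (deterministic; tolerance `tol`). The 95%
#' confidence interval is a leave-one-out jackknife by default; a
#' percentile bootstrap is available with an explicit seed.
#'
#' @param paired paired-measurement `data.frame` (see
#'   [paired_measurements()]); records missing any of `c_b`, `c_pl`, `hct`
#'   are dropped.
#' @param analyte optional analyte filter (`"PARENT"`/`"METABOLITE"`).
#' @param timepoint optional timepoint filter (`"TROUGH"`/`"PEAK"`); by
#'   default all complete records are pooled.
#' @param interval search interval for K.
#' @param tol convergence tolerance of the scalar minimizer.
#' @param ci `"jackknife"` (default) or `"bootstrap"`.
#' @param boot number of bootstrap resamples when `ci = "bootstrap"`.
#' @param seed seed for the bootstrap resampling (required then).
#' @param conf confidence level.
#' @return an object of class `partition_fit` with elements `k_bcpl`, `n`,
#'   `sse`, `se`, `ci_low`, `ci_high`, `conf`, `ci_method`, and
#'   `identifiability_warning` (TRUE when all haematocrits are identical).
#' @examples
#' hct <- rep(c(0.35, 0.40, 0.45, 0.50), each = 2)
#' c_pl <- rep(c(2, 8), times = 4)
#' pm <- paired_measurements(seq_along(hct), "PARENT", "TROUGH",
#'                           blood_from_plasma(c_pl, hct, 1.57), c_pl, hct)
#' estimate_k(pm)
#' @export
estimate_k <- function(paired, analyte = NULL, timepoint = NULL,
                       interval = c(0, 50), tol = 1e-9,
                       ci = c("jackknife", "bootstrap"), boot = 500L,
                       seed = NULL, conf = 0.95) {
  ci <- match.arg(ci)
  df <- validate_paired(as.data.frame(paired), where = "estimate_k()")
  if (!is.null(analyte)) df <- df[df$analyte == as_analyte(analyte), ]
  if (!is.null(timepoint)) df <- df[df$timepoint == toupper(timepoint), ]
  df <- df[complete.cases(df[, c("c_b", "c_pl", "hct")]), ]
  n <- nrow(df)
  if (n < 3L) {
    stop("estimate_k() needs at least 3 complete (c_b, c_pl, hct) records; ",
         "got ", n, call. = FALSE)
  }
  ident_warn <- length(unique(df$hct)) == 1L
  if (ident_warn) {
    warning("all haematocrit values identical: K is estimated from a ",
            "single mixing ratio and is not separately identifiable from ",
            "an assay scale factor", call. = FALSE)
  }

  sse_fun <- function(k, d) {
    sum((d$c_pl - d$c_b / ((1 - d$hct) + k * d$hct))^2)
  }
  fit_one <- function(d) {
    optimize(sse_fun, interval = interval, d = d, tol = tol)$minimum
  }
  k_hat <- fit_one(df)
  sse <- sse_fun(k_hat, df)

  if (ci == "jackknife") {
    k_loo <- vapply(seq_len(n), function(i) fit_one(df[-i, , drop = FALSE]),
                    numeric(1))
    se <- sqrt((n - 1) / n * sum((k_loo - mean(k_loo))^2))
    tcrit <- qt(1 - (1 - conf) / 2, df = n - 1)
    ci_low <- k_hat - tcrit * se
    ci_high <- k_hat + tcrit * se
  } else {
    if (is.null(seed)) {
      stop("bootstrap CI requires an explicit seed", call. = FALSE)
    }
    set.seed(seed)
    k_boot <- vapply(seq_len(boot), function(b) {
      fit_one(df[sample.int(n, n, replace = TRUE), , drop = FALSE])
    }, numeric(1))
    se <- sd(k_boot)
    qs <- quantile(k_boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                   names = FALSE)
    ci_low <- min(qs[1], k_hat)
    ci_high <- max(qs[2], k_hat)
  }

  structure(list(k_bcpl = k_hat, n = n, sse = sse, se = se,
                 ci_low = ci_low, ci_high = ci_high, conf = conf,
                 ci_method = ci, identifiability_warning = ident_warn),
            class = "partition_fit")
}

#' @export
print.partition_fit <- function(x, digits = 4, ...) {
  cat("Blood-cell-to-plasma partition coefficient (nonlinear least squares)\n")
  cat(sprintf("  K_BC/PL = %.*g  [%.*g, %.*g] %g%% CI (%s), n = %d\n",
              digits, x$k_bcpl, digits, x$ci_low, digits, x$ci_high,
              100 * x$conf, x$ci_method, x$n))
  cat(sprintf("  SSE (plasma scale) = %.*g (ug/mL)^2\n", digits, x$sse))
  if (isTRUE(x$identifiability_warning)) {
    cat("  warning: all haematocrit values identical\n")
  }
  invisible(x)
}
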