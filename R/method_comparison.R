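# Clinical cross-validation of the DBS assay against plasma:
# weighted Deming regression and Bland-Altman agreement analysis.

# Closed-form Deming slope/intercept from (optionally weighted) moments.
# lambda is the ratio of the y-error variance to the x-error variance, so
# lambda -> Inf recovers OLS of y on x and lambda = 1 is orthogonal
# regression. The estimate minimizes
#   sum_i w_i * (y_i - a - b x_i)^2 / (lambda + b^2).
deming_core <- function(x, y, w, lambda) {
  sw <- sum(w)
  xm <- sum(w * x) / sw
  ym <- sum(w * y) / sw
  sxx <- sum(w * (x - xm)^2)
  syy <- sum(w * (y - ym)^2)
  sxy <- sum(w * (x - xm) * (y - ym))
  if (sxy == 0) {
    if (sxx == 0 && syy == 0) {
      stop("degenerate data: zero variance in both x and y", call. = FALSE)
    }
    # orthogonal objective is symmetric in the slope sign here; report the
    # positive root (method-comparison data are positively associated)
    slope <- sqrt(syy / (lambda * sxx))
  } else {
    slope <- (syy - lambda * sxx +
                sqrt((syy - lambda * sxx)^2 + 4 * lambda * sxy^2)) /
      (2 * sxy)
  }
  c(slope = slope, intercept = ym - slope * xm)
}

jackknife_ci <- function(stats_loo, point, conf) {
  n <- nrow(stats_loo)
  se <- sqrt((n - 1) / n * colSums(sweep(stats_loo, 2,
                                         colMeans(stats_loo))^2))
  tcrit <- qt(1 - (1 - conf) / 2, df = n - 1)
  list(se = se, low = point - tcrit * se, high = point + tcrit * se)
}

#' Deming regression (errors in both variables), optionally weighted
#'
#' Fits `y = intercept + slope * x` allowing measurement error in both
#' variables. `lambda` is the ratio of error variances (y-error over
#' x-error); `lambda = 1` (default) treats both assays as equally imprecise,
#' and `lambda -> Inf` approaches ordinary least squares of `y` on `x`.
#'
#' With `weighting = "none"` the closed-form Deming solution is returned.
#' With `weighting = "inverse_squared_mean"` each pair is weighted by
#' `1 / ((x_i + y_i) / 2)^2`, the standard weighted-Deming convention for
#' assays with proportional (constant-CV) error; the solution is iterated
#' until successive slopes differ by less than `slope_tol`. Confidence
#' intervals are leave-one-out jackknife.
#'
#' @param x comparator concentrations, ug/mL.
#' @param y response concentrations, ug/mL (same length, n >= 3).
#' @param lambda ratio of error variances (y vs x), > 0.
#' @param weighting `"none"` or `"inverse_squared_mean"`.
#' @param conf confidence level for the jackknife intervals.
#' @param max_iter,slope_tol iteration controls for the weighted mode.
#' @return an object of class `deming_fit`: `slope`, `intercept`,
#'   `slope_ci`, `intercept_ci`, `slope_se`, `intercept_se`, `lambda`,
#'   `weighting`, `n`, plus the data for plotting.
#' @examples
#' x <- c(1, 2, 4, 6, 8, 10, 14, 18)
#' deming_fit(x, 1.2 * x + rnorm(8, sd = 0.1))
#' @export
deming_fit <- function(x, y, lambda = 1,
                       weighting = c("none", "inverse_squared_mean"),
                       conf = 0.95, max_iter = 100L, slope_tol = 1e-10) {
  weighting <- match.arg(weighting)
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("Deming regression needs n >= 3 pairs", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  if (var(x) == 0 && var(y) == 0) {
    stop("degenerate data: zero variance in both x and y", call. = FALSE)
  }
  if (weighting == "inverse_squared_mean" && any(x <= 0 | y <= 0)) {
    stop("inverse_squared_mean weighting requires strictly positive ",
         "concentrations", call. = FALSE)
  }

  fit_sub <- function(xi, yi) {
    w <- if (weighting == "none") rep(1, length(xi)) else 4 / (xi + yi)^2
    est <- deming_core(xi, yi, w, lambda)
    for (it in seq_len(max_iter)) {
      est_new <- deming_core(xi, yi, w, lambda)
      if (abs(est_new["slope"] - est["slope"]) < slope_tol) {
        est <- est_new
        break
      }
      est <- est_new
    }
    est
  }

  est <- fit_sub(x, y)
  loo <- t(vapply(seq_len(n), function(i) fit_sub(x[-i], y[-i]), numeric(2)))
  jk <- jackknife_ci(loo, est, conf)

  structure(list(slope = unname(est["slope"]),
                 intercept = unname(est["intercept"]),
                 slope_ci = unname(c(jk$low["slope"], jk$high["slope"])),
                 intercept_ci = unname(c(jk$low["intercept"],
                                         jk$high["intercept"])),
                 slope_se = unname(jk$se["slope"]),
                 intercept_se = unname(jk$se["intercept"]),
                 lambda = lambda, weighting = weighting, n = n,
                 conf = conf, x = x, y = y),
            class = "deming_fit")
}

#' @export
print.deming_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Deming regression (lambda = %g, weighting = %s), n = %d\n",
              x$lambda, x$weighting, x$n))
  cat(sprintf("  slope     %.*g  [%.*g, %.*g] %g%% CI\n", digits, x$slope,
              digits, x$slope_ci[1], digits, x$slope_ci[2], 100 * x$conf))
  cat(sprintf("  intercept %.*g  [%.*g, %.*g] %g%% CI\n", digits,
              x$intercept, digits, x$intercept_ci[1], digits,
              x$intercept_ci[2], 100 * x$conf))
  invisible(x)
}

#' @export
plot.deming_fit <- function(x, xlab = "comparator (ug/mL)",
                            ylab = "response (ug/mL)", ...) {
  plot(x$x, x$y, xlab = xlab, ylab = ylab, ...)
  graphics::abline(a = x$intercept, b = x$slope, col = "blue")
  graphics::abline(a = 0, b = 1, col = "red", lty = 2)
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b` between two measurements of the same quantity:
#' mean difference (bias), its SD (n - 1 denominator), limits of agreement
#' `mean +/- 1.96 * SD`, and a t-based confidence interval for the mean
#' difference.
#'
#' @param a,b paired measurement vectors, ug/mL (n >= 2).
#' @param conf confidence level for the mean-difference interval.
#' @return an object of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `ci_mean_diff`, `n`, plus `means`/`diffs` for
#'   plotting.
#' @examples
#' bland_altman(c(1.0, 2.1, 3.9, 6.2), c(1.1, 2.0, 4.0, 6.0))
#' @export
bland_altman <- function(a, b, conf = 0.95) {
  if (length(a) != length(b)) stop("a and b must have equal length",
                                   call. = FALSE)
  n <- length(a)
  if (n < 2L) stop("Bland-Altman analysis needs n >= 2 pairs",
                   call. = FALSE)
  d <- a - b
  m <- mean(d)
  s <- sd(d)
  tcrit <- qt(1 - (1 - conf) / 2, df = n - 1)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 ci_mean_diff = c(m - tcrit * s / sqrt(n),
                                  m + tcrit * s / sqrt(n)),
                 n = n, conf = conf, means = (a + b) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 4, ...) {
  cat(sprintf("Bland-Altman agreement, n = %d\n", x$n))
  cat(sprintf("  mean difference %.*g ug/mL  [%.*g, %.*g] %g%% CI\n",
              digits, x$mean_diff, digits, x$ci_mean_diff[1], digits,
              x$ci_mean_diff[2], 100 * x$conf))
  cat(sprintf("  limits of agreement [%.*g, %.*g] (mean +/- 1.96 SD)\n",
              digits, x$loa_low, digits, x$loa_high))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "mean of methods (ug/mL)",
                              ylab = "difference (ug/mL)", ...) {
  plot(x$means, x$diffs, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = x$mean_diff, col = "blue")
  graphics::abline(h = c(x$loa_low, x$loa_high), col = "blue", lty = 2)
  graphics::abline(h = x$ci_mean_diff, col = "grey", lty = 3)
  invisible(x)
}

#' Cross-validate DBS against plasma for one analyte
#'
#' Reproduces the four-panel method-comparison layout: (i) Deming regression
#' of whole-blood DBS concentration (response) on measured plasma
#' (comparator) — the slope is then the blood-to-plasma concentration
#' ratio; (ii) plasma concentrations calculated from DBS via the partition
#' model; (iii) Deming regression of calculated on measured plasma (slope
#' near 1 indicates a successful conversion); (iv) Bland-Altman analyses of
#' both the raw (DBS - plasma) and converted (calculated - measured plasma)
#' comparisons.
#'
#' @param paired paired-measurement `data.frame`; only records with
#'   complete `c_b`, `c_pl` and `hct` for `analyte` are used (n >= 3).
#' @param analyte `"PARENT"` or `"METABOLITE"`.
#' @param k `"fit"` to estimate the partition coefficient from the same
#'   records (see [estimate_k()]) or a fixed numeric value (e.g. 0 for an
#'   analyte excluded from blood cells).
#' @param lambda,weighting,conf forwarded to [deming_fit()].
#' @return an object of class `dbs_comparison`: `deming_raw`,
#'   `deming_calc`, `ba_raw`, `ba_calc`, `partition` (a `partition_fit` or
#'   the fixed value), `calculated` (per-record table with `c_pl_calc`),
#'   `analyte`, `n`.
#' @export
compare_dbs_plasma <- function(paired, analyte, k = "fit", lambda = 1,
                               weighting = "inverse_squared_mean",
                               conf = 0.95) {
  analyte <- as_analyte(analyte)
  df <- validate_paired(as.data.frame(paired),
                        where = "compare_dbs_plasma()")
  df <- df[df$analyte == analyte &
             complete.cases(df[, c("c_b", "c_pl", "hct")]), ]
  if (nrow(df) < 3L) {
    stop("compare_dbs_plasma() needs at least 3 complete records for ",
         analyte, "; got ", nrow(df), call. = FALSE)
  }

  deming_raw <- deming_fit(df$c_pl, df$c_b, lambda = lambda,
                           weighting = weighting, conf = conf)
  if (identical(k, "fit")) {
    partition <- estimate_k(df, conf = conf)
    k_val <- partition$k_bcpl
  } else {
    stopifnot(is.numeric(k), length(k) == 1L, k >= 0)
    partition <- k
    k_val <- k
  }
  df$c_pl_calc <- plasma_from_blood(df$c_b, df$hct, k_val)

  deming_calc <- deming_fit(df$c_pl, df$c_pl_calc, lambda = lambda,
                            weighting = weighting, conf = conf)
  ba_raw <- bland_altman(df$c_b, df$c_pl, conf = conf)
  ba_calc <- bland_altman(df$c_pl_calc, df$c_pl, conf = conf)

  structure(list(deming_raw = deming_raw, deming_calc = deming_calc,
                 ba_raw = ba_raw, ba_calc = ba_calc,
                 partition = partition, k = k_val,
                 calculated = df, analyte = analyte, n = nrow(df)),
            class = "dbs_comparison")
}

#' @export
print.dbs_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("DBS vs plasma cross-validation: %s (%s), n = %d\n",
              x$analyte, analyte_label(x$analyte), x$n))
  cat(sprintf("  partition coefficient K_BC/PL = %.*g%s\n", digits, x$k,
              if (inherits(x$partition, "partition_fit")) " (fitted)"
              else " (fixed)"))
  cat("-- DBS (response) vs measured plasma --\n")
  print(x$deming_raw, digits = digits)
  cat("-- calculated vs measured plasma --\n")
  print(x$deming_calc, digits = digits)
  print(x$ba_calc, digits = digits)
  invisible(x)
}
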