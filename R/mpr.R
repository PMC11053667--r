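# Metabolite-to-parent ratio (MPR) screening.
#
# The MPR of trough samples is a proxy for glucuronidation clearance:
# enzyme induction (e.g. co-medication with phenytoin) raises it, inhibition
# or reduced-activity UGT variants lower it, independently of compliance.
# Screening uses Tukey's fences on the cohort MPR distribution with a
# Grubbs test as confirmation.

#' Metabolite-to-parent concentration ratio
#'
#' @param parent parent-drug concentration, ug/mL (> 0).
#' @param metabolite metabolite concentration, ug/mL (>= 0).
#' @return `metabolite / parent` (dimensionless, unrounded; tables report 3
#'   decimals).
#' @examples
#' compute_mpr(3.50, 2.14) # 0.611 at 3 decimals
#' @export
compute_mpr <- function(parent, metabolite) {
  if (any(parent <= 0)) {
    stop("parent concentration must be > 0", call. = FALSE)
  }
  if (any(metabolite < 0)) {
    stop("metabolite concentration must be >= 0", call. = FALSE)
  }
  metabolite / parent
}

#' Tukey's fences outlier screen
#'
#' Quartiles are Tukey hinges (medians of the median-inclusive halves, as
#' in [stats::fivenum()]); the fences are `Q1 - k * IQR` and
#' `Q3 + k * IQR`, and values strictly outside them are flagged.
#'
#' @param values numeric vector (n >= 4).
#' @param k fence multiplier (1.5 by convention).
#' @return list with `q1`, `q3`, `fence_low`, `fence_high`, and `outlier`
#'   (logical vector aligned with `values`).
#' @examples
#' tukey_fences(compute_mpr(ltg_trough_cohort()$parent_conc,
#'                          ltg_trough_cohort()$metabolite_conc))
#' @export
tukey_fences <- function(values, k = 1.5) {
  if (length(values) < 4L) {
    stop("Tukey fences need n >= 4 values", call. = FALSE)
  }
  fn <- fivenum(values)
  q1 <- fn[2]
  q3 <- fn[4]
  iqr <- q3 - q1
  fence_low <- q1 - k * iqr
  fence_high <- q3 + k * iqr
  list(q1 = q1, q3 = q3, fence_low = fence_low, fence_high = fence_high,
       outlier = values < fence_low | values > fence_high)
}

#' Grubbs test for a single outlier
#'
#' Maximum studentized deviation `G = max|x_i - mean| / sd`, computed on the
#' raw or log scale. The two-sided p-value uses the t-distribution form
#' `p = min(1, 2n * P(T_{n-2} >= t))` with
#' `t = sqrt(n (n-2) G^2 / ((n-1)^2 - n G^2))`; `G^2 >= (n-1)^2 / n` (the
#' attainable maximum) gives p = 0 exactly. MPR distributions are
#' right-skewed, so the log scale is the default for ratio data.
#'
#' @param values numeric vector (n >= 3; all > 0 when `scale = "log"`).
#' @param scale `"log"` (default) or `"raw"`.
#' @return list with `g`, `p` (two-sided), `index` (position of the most
#'   extreme value), `n`, `scale`.
#' @examples
#' grubbs_test(compute_mpr(ltg_trough_cohort()$parent_conc,
#'                         ltg_trough_cohort()$metabolite_conc))
#' @export
grubbs_test <- function(values, scale = c("log", "raw")) {
  scale <- match.arg(scale)
  n <- length(values)
  if (n < 3L) stop("Grubbs test needs n >= 3 values", call. = FALSE)
  if (scale == "log") {
    if (any(values <= 0)) {
      stop("log-scale Grubbs test requires strictly positive values",
           call. = FALSE)
    }
    x <- log(values)
  } else {
    x <- values
  }
  s <- sd(x)
  if (s == 0) stop("degenerate data: zero standard deviation",
                   call. = FALSE)
  dev <- abs(x - mean(x))
  idx <- which.max(dev)
  g <- dev[idx] / s
  gmax_sq <- (n - 1)^2 / n
  if (g^2 >= gmax_sq) {
    p <- 0
  } else {
    tstat <- sqrt(n * (n - 2) * g^2 / ((n - 1)^2 - n * g^2))
    p <- min(1, 2 * n * pt(tstat, df = n - 2, lower.tail = FALSE))
  }
  list(g = g, p = p, index = idx, n = n, scale = scale)
}

#' Summarize a trough cohort: MPRs, fences, Grubbs confirmation
#'
#' Computes per-subject metabolite-to-parent ratios from a trough table,
#' cohort means and SDs (n - 1) of dose, concentrations and MPR, Tukey's
#' fences with per-subject outlier flags, and a Grubbs test on the
#' configured scale.
#'
#' @param trough `data.frame` with columns `subject_id`, `dose` (mg/day),
#'   `parent_conc`, `metabolite_conc` (ug/mL); >= 2 subjects, unique ids,
#'   parent concentrations > 0.
#' @param fence_k Tukey fence multiplier.
#' @param grubbs_scale `"log"` or `"raw"`.
#' @return an object of class `mpr_table`: `table` (per-subject rows with
#'   `mpr` and `outlier`), `cohort` (means/SDs), `fences`, `grubbs`.
#'   Fences and the Grubbs test require n >= 4 and n >= 3 respectively and
#'   are `NULL` below that.
#' @examples
#' summarize_cohort(ltg_trough_cohort())
#' @export
summarize_cohort <- function(trough, fence_k = 1.5,
                             grubbs_scale = c("log", "raw")) {
  grubbs_scale <- match.arg(grubbs_scale)
  req <- c("subject_id", "dose", "parent_conc", "metabolite_conc")
  stopifnot(all(req %in% names(trough)))
  if (nrow(trough) < 2L) {
    stop("cohort summary needs >= 2 subjects", call. = FALSE)
  }
  if (anyDuplicated(trough$subject_id)) {
    stop("duplicate subject ids: ",
         paste(unique(trough$subject_id[duplicated(trough$subject_id)]),
               collapse = ", "), call. = FALSE)
  }
  mpr <- compute_mpr(trough$parent_conc, trough$metabolite_conc)
  tab <- data.frame(subject_id = as.character(trough$subject_id),
                    dose = trough$dose,
                    parent_conc = trough$parent_conc,
                    metabolite_conc = trough$metabolite_conc,
                    mpr = mpr, stringsAsFactors = FALSE)
  fences <- if (nrow(tab) >= 4L) tukey_fences(mpr, k = fence_k) else NULL
  tab$outlier <- if (is.null(fences)) NA else fences$outlier
  grubbs <- if (nrow(tab) >= 3L) grubbs_test(mpr, scale = grubbs_scale)
            else NULL
  cohort <- data.frame(
    statistic = c("mean", "sd"),
    dose = c(mean(tab$dose), sd(tab$dose)),
    parent_conc = c(mean(tab$parent_conc), sd(tab$parent_conc)),
    metabolite_conc = c(mean(tab$metabolite_conc),
                        sd(tab$metabolite_conc)),
    mpr = c(mean(mpr), sd(mpr)), stringsAsFactors = FALSE)
  structure(list(table = tab, cohort = cohort, fences = fences,
                 grubbs = grubbs, fence_k = fence_k),
            class = "mpr_table")
}

#' @export
print.mpr_table <- function(x, ...) {
  cat("Metabolite-to-parent ratio screen,", nrow(x$table), "subjects\n")
  tab <- x$table
  tab$mpr <- sprintf("%.3f", tab$mpr)
  print(tab, row.names = FALSE)
  cat(sprintf("  cohort MPR mean %.3f, SD %.3f\n", x$cohort$mpr[1],
              x$cohort$mpr[2]))
  if (!is.null(x$fences)) {
    cat(sprintf("  Tukey fences (k = %g): [%.4f, %.4f]; %d flagged\n",
                x$fence_k, x$fences$fence_low, x$fences$fence_high,
                sum(x$table$outlier)))
  }
  if (!is.null(x$grubbs)) {
    cat(sprintf("  Grubbs (%s scale): G = %.3f, two-sided p = %.3f\n",
                x$grubbs$scale, x$grubbs$g, x$grubbs$p))
  }
  invisible(x)
}
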