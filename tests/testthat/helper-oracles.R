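# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Grid-search minimizer of the (weighted) Deming orthogonal objective
#   sum_i w_i (y_i - a - b x_i)^2 / (lambda + b^2)
# over (slope, intercept), successively refined to `final_step`.
grid_deming_oracle <- function(x, y, w = rep(1, length(x)), lambda = 1,
                               slope_range = c(0.05, 5),
                               final_step = 1e-5) {
  obj <- function(b, a) sum(w * (y - a - b * x)^2) / (lambda + b^2)
  # intercept minimizing the objective at fixed slope is the weighted mean
  # of y - b x, so search slope on a grid and refine around the best
  a_of <- function(b) sum(w * (y - b * x)) / sum(w)
  lo <- slope_range[1]
  hi <- slope_range[2]
  step <- (hi - lo) / 400
  best <- NA
  while (step >= final_step / 4) {
    bs <- seq(lo, hi, by = step)
    vals <- vapply(bs, function(b) obj(b, a_of(b)), numeric(1))
    best <- bs[which.min(vals)]
    lo <- best - 2 * step
    hi <- best + 2 * step
    step <- step / 10
  }
  c(slope = best, intercept = a_of(best))
}

# Tukey hinges by direct construction: median-inclusive halves.
hinge_oracle <- function(x) {
  s <- sort(x)
  n <- length(s)
  half <- if (n %% 2 == 0) s[seq_len(n / 2)] else s[seq_len((n + 1) / 2)]
  upper <- if (n %% 2 == 0) s[(n / 2 + 1):n] else s[((n + 1) / 2):n]
  c(q1 = median(half), q3 = median(upper))
}

# Grubbs p-value by numeric integration of the t density rather than pt().
grubbs_p_integrate <- function(g, n) {
  if (g^2 >= (n - 1)^2 / n) return(0)
  tstat <- sqrt(n * (n - 2) * g^2 / ((n - 1)^2 - n * g^2))
  tail <- integrate(function(u) dt(u, df = n - 2), lower = tstat,
                    upper = Inf)$value
  min(1, 2 * n * tail)
}

# Small reusable fixtures ----------------------------------------------

trough9 <- function() ltg_trough_cohort()

make_paired_csv <- function(path, df = NULL) {
  if (is.null(df)) {
    df <- paired_measurements(
      subject_id = c("a", "a", "b"),
      analyte = c("PARENT", "METABOLITE", "PARENT"),
      timepoint = c("TROUGH", "TROUGH", "PEAK"),
      c_b = c(3.5, 1.2, 5.1), c_pl = c(2.9, NA, 4.2),
      hct = c(0.45, NA, 0.41))
  }
  write_paired_table(df, path)
  df
}
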