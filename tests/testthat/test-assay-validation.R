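cal_levels <- c(0.1, 0.25, 0.5, 0.75, 1, 5, 7.5, 10, 12.5, 17.5, 20)

test_that("calibration fitting recovers an exact line at the 11 levels", {
  obs <- data.frame(analyte = "PARENT", nominal_conc = cal_levels,
                    response_ratio = 0.1683 * cal_levels - 0.0012)
  fit <- fit_calibration(obs)
  expect_equal(fit$slope, 0.1683, tolerance = 1e-10)
  expect_equal(fit$intercept, -0.0012, tolerance = 1e-8)
  expect_equal(fit$r2, 1)
  expect_equal(fit$n_levels, 11L)
  expect_equal(fit$residuals$bias_pct, rep(0, 11), tolerance = 1e-6)
})

test_that("noise-free recovery holds for arbitrary generating lines", {
  set.seed(21)
  for (i in 1:5) {
    slope <- runif(1, 0.05, 2)
    intercept <- runif(1, -0.01, 0.05)
    obs <- data.frame(nominal_conc = cal_levels,
                      response_ratio = slope * cal_levels + intercept)
    fit <- fit_calibration(obs)
    expect_equal(fit$slope, slope, tolerance = 1e-10)
    expect_equal(fit$intercept, intercept, tolerance = 1e-10)
  }
})

test_that("calibration design errors are raised", {
  expect_error(fit_calibration(data.frame(nominal_conc = c(1, 2, 3, 4, 5),
                                          response_ratio = 1:5 / 10)),
               ">= 6 distinct")
  flat <- data.frame(nominal_conc = cal_levels,
                     response_ratio = rep(0.5, 11))
  expect_error(fit_calibration(flat), "slope")
})

test_that("back-calculation inverts the curve and is not clipped", {
  obs <- data.frame(nominal_conc = cal_levels,
                    response_ratio = 2 * cal_levels)
  curve <- fit_calibration(obs)
  expect_equal(back_calculate(curve, curve$intercept), 0)
  expect_equal(back_calculate(curve, 5), 2.5)
  # round trip across the calibration range
  pred <- curve$intercept + curve$slope * cal_levels
  expect_equal(back_calculate(curve, pred), cal_levels)
  # sub-blank response goes negative, flagged not clipped
  expect_lt(back_calculate(curve, curve$intercept - 0.1), 0)
  expect_equal(flag_blq(c(0.05, 0.2), lloq = 0.1), c(TRUE, FALSE))
})

test_that("LLOQ acceptance combines CV, bias and signal-ratio rules", {
  # CV 19.2%, accuracy 102% and a 6-fold signal pass all three rules
  set.seed(4)
  reps <- c(0.085, 0.102, 0.131, 0.095, 0.097)
  res <- lloq_check(reps, nominal = 0.1, blank_signal = 1,
                    lloq_signal = 6)
  expect_equal(res$cv_pct, 100 * sd(reps) / mean(reps))
  expect_true(res$pass_cv && res$pass_signal)

  high_cv <- c(0.07, 0.1, 0.13, 0.08, 0.14)
  stopifnot(100 * sd(high_cv) / mean(high_cv) > 20)
  expect_false(lloq_check(high_cv, 0.1, 1, 6)$pass)

  expect_false(lloq_check(reps, 0.1, 1, 4.9)$pass_signal)
  expect_true(lloq_check(reps, 0.1, 0, 4.9)$pass_signal)
  expect_equal(lloq_check(reps, 0.1, 0, 1)$signal_ratio, Inf)
})

test_that("QC statistics reproduce hand-computed bias and CV", {
  # mean found 3.11 at nominal 3.0 is +3.7% bias
  found <- data.frame(level = 3, day = 1, found = c(3.11, 3.11))
  st <- qc_stats(found)
  expect_equal(st$bias_pct[st$scope == "INTRA_DAY"], 100 * 0.11 / 3,
               tolerance = 1e-10)

  exact <- data.frame(level = 3, day = rep(1:2, each = 3),
                      found = rep(3, 6))
  st <- qc_stats(exact)
  expect_equal(st$bias_pct, rep(0, 3))
  expect_equal(st$cv_pct, rep(0, 3))

  pair <- qc_stats(data.frame(level = 3, day = 1, found = c(2, 4)))
  expect_equal(pair$mean_found, 3)
  expect_equal(pair$bias_pct, 0)
  expect_equal(pair$cv_pct, 100 * sqrt(2) / 3)
})

test_that("inter-day statistics pool replicates across days", {
  found <- data.frame(level = 3, day = rep(1:3, each = 5),
                      found = c(rnorm(5, 3.1, 0.05), rnorm(5, 2.9, 0.05),
                                rnorm(5, 3.0, 0.05)))
  st <- qc_stats(found)
  inter <- st[st$scope == "INTER_DAY", ]
  expect_equal(inter$n, 15L)
  expect_equal(inter$mean_found, mean(found$found))
  expect_equal(inter$cv_pct, 100 * sd(found$found) / mean(found$found))
})

test_that("QC bias is translation-consistent", {
  set.seed(22)
  found <- data.frame(level = 3, day = rep(1:3, each = 5),
                      found = 3 * exp(rnorm(15, 0, 0.05)))
  base <- qc_stats(found)
  delta <- 0.25
  shifted <- found
  shifted$found <- shifted$found + delta
  sh <- qc_stats(shifted)
  expect_equal(sh$bias_pct, base$bias_pct + 100 * delta / 3,
               tolerance = 1e-10)
})

test_that("matrix-effect slope RSD verdicts follow the threshold", {
  expect_equal(matrix_effect_slopes(rep(0.17, 5))$rsd_pct, 0)
  expect_true(matrix_effect_slopes(rep(0.17, 5))$pass)
  # RSD exactly 3.0%: mean 1, sd 0.03
  s <- 1 + 0.03 * c(-1, -0.5, 0, 0.5, 1) / sd(c(-1, -0.5, 0, 0.5, 1))
  me <- matrix_effect_slopes(s)
  expect_equal(me$rsd_pct, 100 * sd(s) / mean(s))
  expect_true(me$pass)
  spread <- matrix_effect_slopes(c(1.0, 1.1, 1.2, 1.3, 1.4))
  expect_equal(spread$rsd_pct, 13.17616, tolerance = 1e-5)
  expect_false(spread$pass)
  expect_error(matrix_effect_slopes(c(1, 1.1)), ">= 3 lots")
  expect_error(matrix_effect_slopes(c(-2, 1, 0.5)), "> 0")
})

test_that("recovery is the A/B percentage with replicate CV", {
  expect_equal(recovery(1, 1)$mean_pct, 100)
  expect_equal(recovery(0.95, 1.0)$recovery_pct, 95)
  const <- recovery(c(0.9, 0.9, 0.9), c(1, 1, 1))
  expect_equal(const$cv_pct, 0)
  expect_error(recovery(1, 0), "> 0")
})

test_that("haematocrit effect cells carry thresholds and verdicts", {
  # one cell at +13.45% bias, tiny CV: inside the +/-15% bound
  found <- rbind(
    data.frame(hct = 0.55, level = 0.3,
               found = 0.3 * 1.1345 * c(0.999, 1.000, 1.001)),
    data.frame(hct = 0.25, level = 0.3,
               found = 0.3 * c(0.99, 1.00, 1.01)))
  et <- hct_effect(found)
  cell <- et[et$condition == 0.55, ]
  expect_equal(cell$bias_pct, 13.45, tolerance = 1e-2)
  expect_true(cell$pass)
  expect_true(all(et$threshold == 15))

  over <- rbind(
    data.frame(hct = 0.45, level = 3, found = 3 * 1.151 * c(1, 1, 1)),
    data.frame(hct = 0.25, level = 3, found = 3 * c(1, 1, 1)))
  et2 <- hct_effect(over)
  expect_false(et2$pass[et2$condition == 0.45])
  expect_true(et2$pass[et2$condition == 0.25])

  # verdict equals an independent recomputation per cell
  for (i in seq_len(nrow(et2))) {
    v <- over$found[over$hct == et2$condition[i] &
                      over$level == et2$level[i]]
    bias <- 100 * (mean(v) - et2$level[i]) / et2$level[i]
    cv <- 100 * sd(v) / mean(v)
    expect_equal(et2$pass[i], abs(bias) <= 15 && cv <= 15)
  }
})

test_that("all-accurate haematocrit tables pass everywhere", {
  found <- expand.grid(hct = c(0.25, 0.35, 0.45, 0.55),
                       level = c(0.3, 3, 15), rep = 1:3)
  found$found <- found$level
  et <- hct_effect(found)
  expect_true(all(et$pass))
  expect_equal(et$bias_pct, rep(0, nrow(et)))
})

test_that("spot-volume effect needs a reference and reports CV", {
  ratios <- expand.grid(volume = c(10, 20, 30, 40), rep = 1:3)
  ratios$ratio <- 0.5
  ve <- volume_effect(ratios, reference_volume = 10)
  expect_equal(ve$cv_pct, 0)
  expect_equal(ve$per_volume$pct_of_reference, rep(100, 4))

  expect_error(volume_effect(ratios, reference_volume = 15),
               "reference volume")
  single <- data.frame(volume = 10, ratio = c(0.5, 0.51))
  expect_error(volume_effect(single), ">= 2 spot volumes")
})

test_that("stability percent-remaining verdicts follow 100 +/- 15", {
  fresh <- data.frame(level = c(0.3, 15), found = c(0.3, 15))
  stored <- data.frame(condition = rep(c("28 days at 25 C",
                                         "5 days at -20 C"), each = 2),
                       level = rep(c(0.3, 15), 2),
                       found = c(0.892 * 0.3, 0.933 * 15, 0.3, 15))
  et <- stability_ratios(stored, fresh)
  expect_equal(et$pct_remaining[1], 89.2, tolerance = 1e-10)
  expect_true(all(et$pass))

  low <- data.frame(condition = "x", level = 0.3, found = 0.849 * 0.3)
  expect_false(stability_ratios(low, fresh)$pass)
  zero <- data.frame(level = 0.3, found = 0)
  expect_error(stability_ratios(low, zero), "fresh mean")
})
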