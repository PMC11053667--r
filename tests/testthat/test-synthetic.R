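test_that("generation is deterministic in the seed", {
  sc <- synthetic_config(seed = 99, n_subjects = 12)
  co1 <- generate_cohort(sc)
  co2 <- generate_cohort(sc)
  expect_identical(co1, co2)
  expect_identical(generate_paired(co1, sc), generate_paired(co2, sc))
  expect_identical(generate_calibration_run(sc, 2, 2),
                   generate_calibration_run(sc, 2, 2))
  expect_identical(generate_qc_run(sc), generate_qc_run(sc))
  # a different seed changes the draw
  co3 <- generate_cohort(synthetic_config(seed = 100, n_subjects = 12))
  expect_false(identical(co1$hct, co3$hct))
})

test_that("haematocrit draws match the configured truncated normal", {
  sc <- synthetic_config(seed = 2, n_subjects = 10000)
  co <- generate_cohort(sc)
  expect_true(all(co$hct >= 0.25 & co$hct <= 0.55))
  expect_equal(mean(co$hct), 0.42, tolerance = 0.01)
  expect_true(all(co$dose %in% c(100, 200, 250, 300, 400)))
  expect_true(all(co$parent_trough_pl >= 0.1 & co$parent_trough_pl <= 20))
  expect_true(all(co$parent_peak_pl >= co$parent_trough_pl))
})

test_that("outlier spec multiplies the subject's MPR by the exact fold", {
  base <- synthetic_config(seed = 5, n_subjects = 9)
  shifted <- synthetic_config(seed = 5, n_subjects = 9,
                              outlier_spec = list(list(subject = 4,
                                                       fold = 3)))
  co_b <- generate_cohort(base)
  co_s <- generate_cohort(shifted)
  expect_equal(co_s$mpr[4], 3 * co_b$mpr[4])
  expect_equal(co_s$mpr[-4], co_b$mpr[-4])
  expect_error(synthetic_config(outlier_spec = list(list(subject = 10,
                                                         fold = 2))),
               "out of range")
})

test_that("paired records follow the partition model before noise", {
  sc <- synthetic_config(seed = 6, n_subjects = 10, meas_cv = 0)
  co <- generate_cohort(sc)
  pp <- generate_paired(co, sc)
  expect_equal(nrow(pp), 40L) # 10 subjects x 2 analytes x 2 timepoints
  expect_equal(pp$c_b, pp$true_c_b)
  expect_equal(pp$c_pl, pp$true_c_pl)
  met <- pp[pp$analyte == "METABOLITE", ]
  expect_equal(met$c_b, met$c_pl * (1 - met$hct))
  fit <- estimate_k(pp, analyte = "PARENT")
  expect_equal(fit$k_bcpl, 1.57, tolerance = 1e-6)
})

test_that("multiplicative noise has the configured coefficient of variation", {
  sc <- synthetic_config(seed = 7, n_subjects = 50, meas_cv = 0.05)
  pp <- generate_paired(generate_cohort(sc), sc)
  rel <- c(pp$c_b / pp$true_c_b, pp$c_pl / pp$true_c_pl)
  expect_gte(sd(rel) / mean(rel), 0.04)
  expect_lte(sd(rel) / mean(rel), 0.06)
})

test_that("noise-free calibration runs return the configured line", {
  sc <- synthetic_config(seed = 8, meas_cv = 0, lot_slope_rsd = 0)
  cal <- generate_calibration_run(sc, n_lots = 1, n_days = 1)
  expect_equal(sum(cal$analyte == "PARENT"), 11L)
  fitp <- fit_calibration(cal[cal$analyte == "PARENT", ])
  expect_equal(fitp$slope, 0.1683, tolerance = 1e-10)
  expect_equal(fitp$intercept, -0.0012, tolerance = 1e-10)
  expect_equal(fitp$r2, 1)
  fitm <- fit_calibration(cal[cal$analyte == "METABOLITE", ])
  expect_equal(fitm$slope, 1.1243, tolerance = 1e-10)
})

test_that("between-lot slope variation lands near the configured RSD", {
  sc <- synthetic_config(seed = 9, meas_cv = 0, lot_slope_rsd = 0.02)
  cal <- generate_calibration_run(sc, n_lots = 5, n_days = 1)
  slopes <- vapply(sprintf("lot%02d", 1:5), function(l) {
    fit_calibration(cal[cal$analyte == "PARENT" & cal$lot == l, ])$slope
  }, numeric(1))
  me <- matrix_effect_slopes(slopes, threshold = 4)
  expect_lt(me$rsd_pct, 4)
  expect_true(me$pass)
})

test_that("QC runs reproduce injected bias and inter-day CV envelope", {
  sc0 <- synthetic_config(seed = 10, meas_cv = 0)
  qc0 <- generate_qc_run(sc0)
  st0 <- qc_stats(qc0[qc0$analyte == "PARENT", ])
  expect_equal(st0$bias_pct, rep(0, nrow(st0)))
  expect_equal(st0$cv_pct, rep(0, nrow(st0)))

  # +3.7% injected at the mid level is recovered up to sampling error
  sc <- synthetic_config(seed = 11)
  qc <- generate_qc_run(sc, levels = 3, level_bias = 0.037,
                        n_reps = 60, n_days = 3)
  st <- qc_stats(qc[qc$analyte == "PARENT", ])
  inter <- st[st$scope == "INTER_DAY", ]
  expect_equal(inter$bias_pct, 3.7, tolerance = 1.5)

  # Monte-Carlo envelope on the inter-day CV at 5% measurement noise
  hit <- 0L
  n_seeds <- 500L
  for (s in seq_len(n_seeds)) {
    qi <- generate_qc_run(synthetic_config(seed = 20000 + s), levels = 3,
                          analytes = "PARENT")
    sti <- qc_stats(qi)
    cv <- sti$cv_pct[sti$scope == "INTER_DAY"]
    if (cv >= 2 && cv <= 9) hit <- hit + 1L
  }
  expect_gte(hit / n_seeds, 0.95)

  expect_error(generate_qc_run(sc, levels = 30), "calibration range")
})

test_that("the noise-free pipeline reproduces all generating parameters", {
  sc <- synthetic_config(seed = 12, n_subjects = 9, meas_cv = 0,
                         lot_slope_rsd = 0)
  co <- generate_cohort(sc)
  pp <- generate_paired(co, sc)
  expect_equal(estimate_k(pp, analyte = "PARENT")$k_bcpl, 1.57,
               tolerance = 1e-6)
  expect_equal(estimate_k(pp, analyte = "METABOLITE")$k_bcpl, 0,
               tolerance = 1e-6)
  cal <- generate_calibration_run(sc)
  expect_equal(fit_calibration(cal[cal$analyte == "PARENT", ])$slope,
               0.1683, tolerance = 1e-6 * 0.1683)
  # trough DBS records reproduce each subject's MPR exactly:
  # the partition factor cancels only partially, so compare on plasma
  parent <- pp[pp$analyte == "PARENT" & pp$timepoint == "TROUGH", ]
  met <- pp[pp$analyte == "METABOLITE" & pp$timepoint == "TROUGH", ]
  expect_equal(met$c_pl / parent$c_pl, co$mpr, tolerance = 1e-10)
})
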