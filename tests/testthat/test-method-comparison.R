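test_that("Deming regression is exact on error-free lines", {
  x <- c(0.3, 1, 2.5, 6, 9, 14, 17, 20)
  for (wt in c("none", "inverse_squared_mean")) {
    fit <- deming_fit(x, x, weighting = wt)
    expect_equal(fit$slope, 1)
    expect_equal(fit$intercept, 0)
    half <- deming_fit(x, 0.5 * x, weighting = wt)
    expect_equal(half$slope, 0.5)
    expect_equal(half$intercept, 0, tolerance = 1e-12)
  }
})

test_that("closed-form Deming matches the grid-search orthogonal oracle", {
  set.seed(31)
  for (rep in 1:4) {
    x <- runif(8, 1, 15)
    y <- 1.2 * x + 0.3 + rnorm(8, sd = 0.6)
    fit <- deming_fit(x, y, weighting = "none")
    oracle <- grid_deming_oracle(x, y)
    expect_equal(fit$slope, unname(oracle["slope"]), tolerance = 1e-3)
    expect_equal(fit$intercept, unname(oracle["intercept"]),
                 tolerance = 1e-3)
  }
})

test_that("weighted Deming matches the weighted grid-search oracle", {
  set.seed(32)
  for (rep in 1:4) {
    x <- runif(10, 0.5, 18)
    y <- (0.8 * x + 0.1) * exp(rnorm(10, 0, 0.06))
    fit <- deming_fit(x, y, weighting = "inverse_squared_mean")
    oracle <- grid_deming_oracle(x, y, w = 4 / (x + y)^2)
    expect_equal(fit$slope, unname(oracle["slope"]), tolerance = 1e-3)
    expect_equal(fit$intercept, unname(oracle["intercept"]),
                 tolerance = 1e-3)
  }
})

test_that("lambda -> Inf approaches ordinary least squares of y on x", {
  set.seed(33)
  x <- runif(20, 1, 10)
  y <- 2 * x + 1 + rnorm(20, sd = 0.5)
  fit <- deming_fit(x, y, lambda = 1e8)
  ols <- coef(lm(y ~ x))
  expect_equal(fit$slope, unname(ols[2]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(ols[1]), tolerance = 1e-5)
})

test_that("Deming slope is scale-equivariant in y", {
  set.seed(34)
  x <- runif(12, 1, 10)
  y <- 1.5 * x + rnorm(12, sd = 0.3)
  base <- deming_fit(x, y)
  # rescaling y by c rescales its error variance by c^2, so the
  # equivariant comparison uses lambda = c^2
  for (cc in c(0.5, 3)) {
    scaled <- deming_fit(x, cc * y, lambda = cc^2)
    expect_equal(scaled$slope, cc * base$slope)
    expect_equal(scaled$intercept, cc * base$intercept)
  }
})

test_that("Deming rejects degenerate or invalid inputs", {
  expect_error(deming_fit(rep(2, 5), rep(3, 5)), "zero variance")
  expect_error(deming_fit(1:5, 1:4), "equal length")
  expect_error(deming_fit(1:2, 1:2), "n >= 3")
  expect_error(deming_fit(c(-1, 2, 3), c(1, 2, 3),
                          weighting = "inverse_squared_mean"),
               "positive")
  expect_error(deming_fit(1:5, 1:5, lambda = 0), "lambda")
})

test_that("Bland-Altman statistics match hand arithmetic", {
  eq <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$mean_diff, 0)
  expect_equal(eq$sd_diff, 0)
  expect_equal(c(eq$loa_low, eq$loa_high), c(0, 0))

  const <- bland_altman(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_equal(const$mean_diff, 1)
  expect_equal(const$sd_diff, 0)
  expect_equal(const$ci_mean_diff, c(1, 1))

  two <- bland_altman(c(1, 3), c(1, 1))
  expect_equal(two$mean_diff, 1)
  expect_equal(two$sd_diff, sqrt(2))
  expect_equal(two$loa_low, 1 - 1.96 * sqrt(2))
  expect_equal(two$loa_high, 1 + 1.96 * sqrt(2))

  expect_error(bland_altman(1, 1), "n >= 2")
})

test_that("Bland-Altman mean difference is antisymmetric", {
  set.seed(35)
  a <- runif(10, 1, 10)
  b <- a * exp(rnorm(10, 0, 0.1))
  expect_equal(bland_altman(a, b)$mean_diff, -bland_altman(b, a)$mean_diff)
})

test_that("noise-free cohorts convert to the identity comparison", {
  sc <- synthetic_config(seed = 3, n_subjects = 12, meas_cv = 0)
  pp <- generate_paired(generate_cohort(sc), sc)
  for (an in c("PARENT", "METABOLITE")) {
    cp <- compare_dbs_plasma(pp, an, k = "fit")
    expect_equal(cp$deming_calc$slope, 1, tolerance = 1e-7)
    expect_equal(cp$deming_calc$intercept, 0, tolerance = 1e-7)
    expect_equal(cp$ba_calc$mean_diff, 0, tolerance = 1e-8)
  }
})

test_that("metabolite blood-to-plasma slope tracks the plasma fraction", {
  # with K = 0 the model gives c_b = c_pl * (1 - hct), so the regression
  # slope of blood on plasma should sit near the cohort's mean 1 - Hct
  sc <- synthetic_config(seed = 8, n_subjects = 60)
  pp <- generate_paired(generate_cohort(sc), sc)
  cp <- compare_dbs_plasma(pp, "METABOLITE", k = 0)
  expected <- mean(1 - pp$hct[pp$analyte == "METABOLITE"])
  expect_gte(expected, cp$deming_raw$slope_ci[1])
  expect_lte(expected, cp$deming_raw$slope_ci[2])
})

test_that("compare_dbs_plasma requires complete records", {
  pm <- paired_measurements(1:2, "PARENT", "TROUGH", c(1, 2), c(1, 2),
                            c(0.4, 0.5))
  expect_error(compare_dbs_plasma(pm, "PARENT"), "at least 3")
})
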