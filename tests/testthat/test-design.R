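test_that("log-log regression recovers exact power laws", {
  expect_equal(fit_loglog_slope(c(1, 4), c(1, 0.5))$slope, -0.5)
  tau <- c(1, 5, 20, 100)
  eps <- 3 * tau^(-0.5)
  f <- fit_loglog_slope(tau, eps)
  expect_equal(f$slope, -0.5, tolerance = 1e-12)
  expect_equal(f$intercept, log(3), tolerance = 1e-12)
  # constant uncertainties give zero slope
  expect_equal(fit_loglog_slope(tau, rep(2, 4))$slope, 0)
  # doubling the uncertainties shifts the intercept by log(2) only
  f2 <- fit_loglog_slope(tau, 2 * eps)
  expect_equal(f2$slope, f$slope)
  expect_equal(f2$intercept - f$intercept, log(2), tolerance = 1e-12)
  expect_error(fit_loglog_slope(tau, c(1, -1, 1, 1)), "positive")
})

test_that("OLS matches the normal equations computed by hand", {
  x <- log(c(1, 3, 10, 30, 100))
  y <- log(c(5, 3.1, 1.55, 0.9, 0.52))
  f <- fit_loglog_slope(exp(x), exp(y))
  n <- length(x)
  slope_ne <- (n * sum(x * y) - sum(x) * sum(y)) /
    (n * sum(x^2) - sum(x)^2)
  intercept_ne <- mean(y) - slope_ne * mean(x)
  expect_equal(f$slope, slope_ne, tolerance = 1e-12)
  expect_equal(f$intercept, intercept_ne, tolerance = 1e-12)
})

test_that("information uncertainties scale exactly as inverse root time", {
  ps <- benchmark_free4()
  scan <- uncertainty_vs_time(ps, std_flux(), std_conds(),
                              time_factors = c(1, 10, 100, 1000))
  expect_true(all(abs(scan$slope + 0.5) < 1e-6))
  # uncertainties at factor 100 are exactly a tenth of factor 1
  expect_equal(scan$uncertainties[3, ], scan$uncertainties[1, ] / 10,
               tolerance = 1e-9)
})

test_that("contrast scan finds the SiO2 contrast-matching minimum", {
  bp <- bilayer_params()
  conds <- list(measurement_condition(0.7, 900, 30),
                measurement_condition(2.0, 3600, 30))
  grid <- seq(-0.56e-6, 6.35e-6, length.out = 40)
  sc <- contrast_scan(bp, grid, std_flux(), conds)
  expect_true(all(sc$fi >= 0))
  imin <- which.min(sc$fi[, "sio2_hydration"])
  inear <- which.min(abs(grid - bp$sio2_sld))
  expect_equal(imin, inear)
})

test_that("a prior contrast never reduces the joint information", {
  bp <- bilayer_params()
  conds <- list(measurement_condition(0.7, 900, 25),
                measurement_condition(2.0, 3600, 25))
  grid <- seq(-0.56e-6, 6.35e-6, length.out = 15)
  single <- contrast_scan(bp, grid, std_flux(), conds)
  joint <- contrast_scan(bp, grid, std_flux(), conds,
                         prior_contrasts = contrast_sld_from_d2o_fraction(1))
  expect_true(all(joint$fi >= single$fi * (1 - 1e-9)))
})

test_that("noise-free replicates show negligible fitting bias", {
  m <- benchmark_model()
  ps <- model_parameter_set(m, c("layer2.thickness", "layer2.sld"))
  dd <- neutronfi:::.design_datasets(ps, std_flux(), std_conds())
  eps <- parameter_uncertainties(fisher_analysis(ps, dd$datasets,
                                                 dd$model_map))
  # deterministic (expected-count) data: the fit must sit on the truth
  ds <- simulate_experiment(m, std_flux(), std_conds(), poisson = FALSE)
  fit <- fit_model(ps, ds, seed = 3, pop_size = 15, max_iter = 30)
  expect_true(all(abs(coef(fit) - ps$values) < 1e-3 * ps$values))
})

test_that("bias estimates are reproducible and carry standard errors", {
  m <- benchmark_model()
  ps <- model_parameter_set(m, c("layer2.thickness", "layer2.sld"))
  conds <- measurement_condition(0.7, 450, 50)
  b1 <- estimate_fit_bias(ps, std_flux(), conds, n_replicates = 2,
                          seed = 5, pop_size = 10, max_iter = 10)
  b2 <- estimate_fit_bias(ps, std_flux(), conds, n_replicates = 2,
                          seed = 5, pop_size = 10, max_iter = 10)
  expect_identical(b1$bias, b2$bias)
  expect_true(all(is.finite(b1$standard_error)))
  expect_equal(b1$failures, 0L)
})

test_that("the Anscombe transform stabilises counts as documented", {
  expect_equal(anscombe_transform(0), 2 * sqrt(3 / 8))
  expect_error(anscombe_transform(-1), ">= 0")
})

test_that("a dataset is statistically indistinguishable from itself", {
  ds <- simulate_experiment(benchmark_model(), std_flux(), std_conds(),
                            seed = 11)
  res <- compare_datasets(ds, ds)
  expect_equal(res$t2, 0)
  expect_equal(res$p, 1)
})

test_that("mismatched binning is refused", {
  d1 <- simulate_measurement(benchmark_model(), std_flux(),
                             measurement_condition(0.7, 450, 30), seed = 1)
  d2 <- simulate_measurement(benchmark_model(), std_flux(),
                             measurement_condition(0.7, 450, 40), seed = 1)
  expect_error(compare_datasets(d1, d2), "binning")
  d3 <- simulate_measurement(benchmark_model(), std_flux(),
                             measurement_condition(2.0, 450, 30), seed = 1)
  expect_error(compare_datasets(d1, d3), "binning")
})

test_that("the comparison test has power against a shifted model", {
  # geometric wavelength grid + flat flux: every geometric Q bin collects
  # the same incident counts, so a reflectivity-level shift moves all
  # per-bin Anscombe differences coherently
  lam <- exp(seq(log(1), log(10), length.out = 1400))
  fl <- flux_profile(lam, rep(1e4, 1400), reference_angle = 0.7)
  cond <- measurement_condition(0.7, 100, 70)
  m <- constant_model(0.5)
  ps <- constant_r_parameter_set(0.5)
  dd <- neutronfi:::.design_datasets(ps, fl, cond)
  eps <- parameter_uncertainties(fisher_analysis(ps, dd$datasets,
                                                 dd$model_map))
  m_shift <- constant_model(0.5 + 10 * eps)
  a <- simulate_measurement(m, fl, cond, seed = 61)
  b <- simulate_measurement(m_shift, fl, cond, seed = 62)
  expect_lt(compare_datasets(a, b)$p, 0.01)
  # and stays calibrated under the null
  a2 <- simulate_measurement(m, fl, cond, seed = 63)
  b2 <- simulate_measurement(m, fl, cond, seed = 64)
  expect_gt(compare_datasets(a2, b2)$p, 0.01)
})
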