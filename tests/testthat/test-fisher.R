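test_that("parameter sets validate names, bounds and builder output", {
  expect_error(parameter_set("a", 1, 2, 3, function(v) list()), "bounds")
  expect_error(parameter_set(c("a", "a"), c(1, 2), c(0, 0), c(3, 3),
                             function(v) list(benchmark_model())), "unique")
  ps <- model_parameter_set(benchmark_model(), "layer2.thickness")
  expect_equal(ps$values, 297.9, ignore_attr = TRUE)
  expect_equal(ps$lower, 297.9 * 0.75, ignore_attr = TRUE)
  expect_error(model_parameter_set(benchmark_model(), "layer9.sld"), "layer")
})

test_that("jacobian columns match analytic derivatives for linear parameters", {
  # reflectivity is linear in the scale factor: dr/dscale = (r - bkg)/scale
  m <- benchmark_model()
  ps <- model_parameter_set(m, c("scale", "layer2.thickness"))
  q <- seq(0.02, 0.25, length.out = 40)
  d <- design_dataset(q, rep(1e5, 40))
  J <- refl_jacobian(ps, d)
  analytic <- (model_reflectivity(q, m) - m$background) / m$scale
  expect_equal(J[, "scale"], analytic, tolerance = 1e-6)
  # thickness perturbations move interference fringes: alternating sign
  expect_gte(sum(diff(sign(J[, "layer2.thickness"])) != 0), 2)
})

test_that("a parameter without influence yields a zero Jacobian column", {
  m <- benchmark_model()
  ps <- parameter_set(
    names = c("layer2.thickness", "inert"),
    values = c(297.9, 5), lower = c(200, 1), upper = c(400, 10),
    build = function(v)
      list(neutronfi:::.set_model_field(m, "layer2.thickness",
                                        unname(v[1]))))
  d <- design_dataset(seq(0.02, 0.25, length.out = 30), rep(1e5, 30))
  J <- refl_jacobian(ps, d)
  expect_true(all(J[, "inert"] == 0))
  expect_gt(max(abs(J[, "layer2.thickness"])), 0)
})

test_that("single-bin single-parameter information equals the Poisson result s/xi", {
  # constant reflectivity r(xi) = xi: the Fisher information of a Poisson
  # mean s*xi with respect to xi is s/xi
  ps <- constant_r_parameter_set(0.5)
  d <- design_dataset(0.1, 2e5)
  fa <- fisher_analysis(ps, d)
  expect_equal(as.numeric(fa$fisher), 2e5 / 0.5, tolerance = 1e-6)
  # and the exact Poisson KL agrees with the quadratic form locally
  delta <- 1e-3
  kl <- kl_divergence_counts(ps, 0.5 + delta, d)
  expect_equal(kl, 0.5 * (2e5 / 0.5) * delta^2, tolerance = 1e-2)
})

test_that("information is linear in incident counts and counting time", {
  ps <- benchmark_free4()
  q <- seq(0.02, 0.25, length.out = 50)
  s <- seq(1e4, 1e6, length.out = 50)
  g1 <- fisher_analysis(ps, design_dataset(q, s))$fisher
  g2 <- fisher_analysis(ps, design_dataset(q, 2 * s))$fisher
  expect_equal(g2, 2 * g1, tolerance = 1e-12)
  # hence uncertainties shrink exactly as 1/sqrt(c)
  expect_equal(parameter_uncertainties(g2),
               parameter_uncertainties(g1) / sqrt(2), tolerance = 1e-10)
})

test_that("parameters acting on disjoint datasets give a block-diagonal information matrix", {
  mk <- function(level) refl_model(refl_structure(2.047e-6, list(),
                                                  backing_sld = 2.047e-6),
                                   scale = 1, background = level)
  ps <- parameter_set(
    names = c("r_a", "r_b"), values = c(0.4, 0.2),
    lower = c(0.1, 0.05), upper = c(0.9, 0.9),
    build = function(v) list(mk(unname(v[1])), mk(unname(v[2]))))
  da <- design_dataset(c(0.05, 0.1), c(1e5, 1e5))
  db <- design_dataset(c(0.2, 0.3), c(2e5, 2e5))
  fa <- fisher_analysis(ps, list(da, db))
  expect_equal(fa$fisher["r_a", "r_b"], 0)
  expect_equal(fa$fisher["r_a", "r_a"], 2e5 / 0.4, tolerance = 1e-6)
  expect_equal(fa$fisher["r_b", "r_b"], 4e5 / 0.2, tolerance = 1e-6)
})

test_that("the information matrix is symmetric positive semi-definite on random fixtures", {
  q <- exp(seq(log(0.01), log(0.3), length.out = 60))
  for (seed in 1:6) {
    s <- random_structure(1L + seed %% 3L, seed = 500 + seed)
    m <- refl_model(s, scale = 1, background = 1e-6,
                    resolution_dq_q = 0.02)
    free <- c("layer1.thickness", "layer1.sld", "backing_roughness")
    ps <- model_parameter_set(m, free)
    fa <- fisher_analysis(ps, design_dataset(q, rep(1e5, 60)))
    expect_equal(fa$fisher, t(fa$fisher))
    ev <- eigen(fa$fisher, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-8 * max(abs(ev))))
  }
})

test_that("exact Poisson KL divergence follows the closed form and vanishes at zero shift", {
  ps <- constant_r_parameter_set(0.5)
  d <- design_dataset(0.1, 200)
  expect_identical(kl_divergence_counts(ps, 0.5, d), 0)
  # lambda 100 -> 110
  expect_equal(kl_divergence_counts(ps, 0.55, d),
               100 * log(100 / 110) - 100 + 110, tolerance = 1e-12)
})

test_that("uncertainties are the root inverse diagonal of the information matrix", {
  expect_equal(parameter_uncertainties(diag(c(4, 25))), c(0.5, 0.2))
  g <- matrix(c(2, 1, 1, 1), 2, 2)
  expect_equal(parameter_uncertainties(g), c(1, sqrt(2)))
  expect_equal(parameter_uncertainties(10 * g),
               c(1, sqrt(2)) / sqrt(10))
})

test_that("singular information matrices are refused with the degenerate direction named", {
  g <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(c("p", "q"),
                                                   c("p", "q")))
  expect_error(parameter_uncertainties(g), "singular")
  expect_error(parameter_uncertainties(g), "degenerate")
})

test_that("confidence ellipses have the documented geometry", {
  ps <- benchmark_free4()
  q <- seq(0.02, 0.25, length.out = 60)
  fa <- fisher_analysis(ps, design_dataset(q, rep(1e6, 60)))
  e1 <- confidence_ellipse(fa, 1, 3, k = 1)
  e3 <- confidence_ellipse(fa, 1, 3, k = 3)
  # k = 3 boundary is the k = 1 boundary scaled threefold about the centre
  expect_equal(sweep(e3$boundary, 2, e1$centre),
               3 * sweep(e1$boundary, 2, e1$centre), tolerance = 1e-9)
  # every sampled point satisfies the quadratic form
  Cinv <- solve(e1$covariance)
  qf <- apply(sweep(e1$boundary, 2, e1$centre), 1,
              function(x) as.numeric(t(x) %*% Cinv %*% x))
  expect_lt(max(abs(qf - 1)), 1e-9)
  # a diagonal information matrix gives an axis-aligned ellipse with
  # semi-axes equal to the marginal uncertainties
  ps2 <- constant_r_parameter_set(0.5)
  g <- diag(c(16, 100))
  dimnames(g) <- list(c("a", "b"), c("a", "b"))
  fake <- structure(list(parameters = list(names = c("a", "b"),
                                           values = c(1, 2)),
                         fisher = g,
                         covariance = solve(g),
                         condition_number = 100 / 16),
                    class = "fisher_analysis")
  e <- confidence_ellipse(fake, "a", "b", k = 1)
  spans <- apply(e$boundary, 2, function(x) diff(range(x)) / 2)
  expect_equal(unname(spans), c(1 / 4, 1 / 10), tolerance = 1e-6)
})

test_that("the negative log-likelihood decomposes into chi-squared and normalisation", {
  m <- constant_model(0.5)
  d0 <- design_dataset(c(0.1, 0.2), c(1e4, 1e4))
  d0$r <- c(0.5, 0.5)
  d0$dr <- c(0.1, 0.2)
  # model reproduces the data: normalisation term only
  expect_equal(negative_log_likelihood(d0, m),
               0.5 * sum(log(2 * pi * d0$dr^2)))
  # one point, residual of two uncertainties: chi-squared term is 1
  d1 <- design_dataset(0.1, 1e4)
  d1$r <- 1
  d1$dr <- 0.5
  expect_equal(negative_log_likelihood(d1, m),
               0.5 * (1 + log(2 * pi * 0.25)))
  # a zero-residual extra point contributes only its normalisation
  d2 <- design_dataset(c(0.1, 0.3), c(1e4, 1e4))
  d2$r <- c(1, 0.5)
  d2$dr <- c(0.5, 0.1)
  expect_equal(negative_log_likelihood(d2, m) -
                 negative_log_likelihood(d1, m),
               0.5 * log(2 * pi * 0.01))
  d1$dr <- 0
  expect_error(negative_log_likelihood(d1, m), "positive uncertainty")
})

test_that("fitting with every parameter fixed returns the input unchanged", {
  ps <- model_parameter_set(benchmark_model(), c("layer2.thickness"))
  ps$fixed <- TRUE
  d <- simulate_measurement(benchmark_model(), std_flux(),
                            measurement_condition(0.7, 450, 40), seed = 1)
  fit <- fit_model(ps, d)
  expect_identical(fit$parameters$values, ps$values)
  expect_equal(fit$generations, 0L)
})

test_that("fitting noise-free data recovers the generating parameters", {
  m <- benchmark_model()
  ps <- model_parameter_set(m, c("layer2.thickness", "layer2.sld"))
  ds <- simulate_experiment(m, std_flux(), std_conds(), poisson = FALSE)
  fit <- fit_model(ps, ds, seed = 1, pop_size = 15, max_iter = 30)
  expect_equal(coef(fit), stats::setNames(ps$values, ps$names),
               tolerance = 1e-3)
})

test_that("fits with the same seed are identical", {
  m <- benchmark_model()
  ps <- model_parameter_set(m, c("layer2.thickness", "layer2.sld"))
  d <- simulate_measurement(m, std_flux(),
                            measurement_condition(0.7, 450, 40), seed = 8)
  f1 <- suppressWarnings(fit_model(ps, d, seed = 21, pop_size = 10,
                                   max_iter = 8, polish = FALSE))
  f2 <- suppressWarnings(fit_model(ps, d, seed = 21, pop_size = 10,
                                   max_iter = 8, polish = FALSE))
  expect_identical(f1$parameters$values, f2$parameters$values)
})

test_that("the MH sampler reproduces a flat posterior and a Gaussian target", {
  ps <- parameter_set("p", 0.5, 0, 1,
                      function(v) list(constant_model(unname(v[1]))))
  flat <- mh_sampler(ps, n_steps = 2e4, seed = 31, proposal_frac = 0.5,
                     log_likelihood = function(v) 0)
  expect_equal(unname(flat$sd), 1 / sqrt(12), tolerance = 0.1)
  gauss <- mh_sampler(ps, n_steps = 1e5, seed = 32,
                      proposal_sd = 0.1,
                      log_likelihood = function(v)
                        -0.5 * ((v - 0.5) / 0.04)^2)
  expect_equal(unname(gauss$sd), 0.04, tolerance = 0.1)
  again <- mh_sampler(ps, n_steps = 1e3, seed = 33, proposal_frac = 0.5,
                      log_likelihood = function(v) 0)
  again2 <- mh_sampler(ps, n_steps = 1e3, seed = 33, proposal_frac = 0.5,
                       log_likelihood = function(v) 0)
  expect_identical(again$samples, again2$samples)
})
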