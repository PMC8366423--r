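test_that("momentum transfer follows 4 pi sin(theta) / lambda", {
  expect_equal(q_from_wavelength(5, 0), 0)
  expect_equal(q_from_wavelength(2 * pi, 30), 1.0)
  expect_equal(q_from_wavelength(1, 0.7), 4 * pi * sin(0.7 * pi / 180))
  expect_error(q_from_wavelength(-1, 0.7), "> 0")
})

test_that("geometric bins have geometric-progression edges and geometric-mean centres", {
  b <- geometric_q_bins(0.01, 0.04, 2)
  expect_equal(b$edges, c(0.01, 0.02, 0.04))
  expect_equal(b$centres, c(sqrt(2) * 1e-2, 2 * sqrt(2) * 1e-2))
  b1 <- geometric_q_bins(0.01, 0.04, 1)
  expect_equal(b1$edges, c(0.01, 0.04))
  ba <- geometric_q_bins(0.01, 0.04, 2, centre = "arithmetic")
  expect_equal(ba$centres, c(0.015, 0.03))
  expect_error(geometric_q_bins(0.04, 0.01, 2), "q_min")
})

test_that("intensity scales as the square of the angle ratio", {
  expect_equal(angle_intensity_factor(0.3, 0.3), 1.0)
  expect_equal(angle_intensity_factor(0.6, 0.3), 4.0)
  expect_equal(angle_intensity_factor(0.15, 0.3), 0.25)
})

test_that("synthetic flux profile meets its normalisation contract", {
  fl <- synthetic_flux_profile(0.5, 12, total_flux = 3e7)
  expect_lt(abs(sum(fl$flux) - 3e7) / 3e7, 1e-3)
  expect_true(all(fl$flux >= 0))
  expect_identical(fl$flux, synthetic_flux_profile(0.5, 12,
                                                   total_flux = 3e7)$flux)
})

test_that("simulation is reproducible and leaves the caller's RNG alone", {
  m <- benchmark_model()
  fl <- std_flux()
  cond <- measurement_condition(0.7, 450, 50)
  set.seed(999)
  before <- runif(1)
  set.seed(999)
  d1 <- simulate_measurement(m, fl, cond, seed = 5)
  after <- runif(1)
  d2 <- simulate_measurement(m, fl, cond, seed = 5)
  expect_identical(d1$counts, d2$counts)
  expect_identical(before, after)
})

test_that("dataset fields satisfy the counting-statistics identities", {
  m <- benchmark_model()
  d <- simulate_measurement(m, std_flux(),
                            measurement_condition(0.7, 450, 60), seed = 3)
  expect_false(is.unsorted(d$q, strictly = TRUE))
  expect_equal(d$dr * d$incident, sqrt(d$counts))
  expect_equal(d$r, d$counts / d$incident)
  pos <- d$counts > 0
  expect_equal(d$dr[pos], d$r[pos] / sqrt(d$counts[pos]))
})

test_that("doubling the counting time doubles incident counts exactly", {
  fl <- std_flux()
  c1 <- measurement_condition(0.7, 450, 60)
  c2 <- measurement_condition(0.7, 900, 60)
  b1 <- neutronfi:::.bin_incident_counts(fl, c1)
  b2 <- neutronfi:::.bin_incident_counts(fl, c2)
  expect_identical(b1$q, b2$q)
  expect_equal(b2$s, 2 * b1$s)
})

test_that("Poisson draws reproduce the first two moments of the count law", {
  m <- constant_model(0.5)
  fl <- std_flux()
  cond <- measurement_condition(0.7, 450, 20)
  s <- neutronfi:::.bin_incident_counts(fl, cond)$s
  n_rep <- 200
  counts <- matrix(NA_real_, nrow = n_rep, ncol = 20)
  for (k in seq_len(n_rep))
    counts[k, ] <- simulate_measurement(m, fl, cond, seed = 7000 + k)$counts
  lambda <- s * 0.5
  # per-bin mean within 4 standard errors of s_i r_i
  se <- sqrt(lambda / n_rep)
  expect_true(all(abs(colMeans(counts) - lambda) < 4 * se))
  # index of dispersion near 1 when pooled over bins
  disp <- apply(counts, 2, var) / colMeans(counts)
  expect_gt(mean(disp), 0.9)
  expect_lt(mean(disp), 1.1)
})

test_that("relative uncertainty contracts as one over root time", {
  m <- benchmark_model()
  fl <- std_flux()
  mean_rel <- vapply(c(1, 4), function(fac) {
    reps <- vapply(1:40, function(k) {
      d <- simulate_measurement(m, fl,
                                measurement_condition(0.7, 450 * fac, 30),
                                seed = 100 * fac + k)
      mean(d$dr / d$r)
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  expect_equal(mean_rel[1] / mean_rel[2], 2, tolerance = 0.05)
})

test_that("zero flux yields an empty dataset with a warning", {
  fl <- flux_profile(c(1, 2, 3), c(0, 0, 0))
  expect_warning(
    d <- simulate_measurement(benchmark_model(), fl,
                              measurement_condition(0.7, 450, 10)),
    "no incident flux")
  expect_length(d$q, 0)
})

test_that("the benchmark two-angle schedule yields 140 usable points", {
  ds <- simulate_experiment(benchmark_model(), std_flux(), std_conds(),
                            seed = 1)
  expect_length(ds, 2)
  expect_equal(sum(vapply(ds, function(d) length(d$q), integer(1))), 140L)
})

test_that("one model and one condition reduce to a single measurement", {
  out <- simulate_experiment(benchmark_model(), std_flux(),
                             measurement_condition(0.7, 450, 30), seed = 2)
  expect_length(out, 1)
  expect_s3_class(out[[1]], "nr_dataset")
})

test_that("identical models receive independent noise sub-streams", {
  m <- benchmark_model()
  ds <- simulate_experiment(list(m, m), std_flux(),
                            measurement_condition(0.7, 450, 50), seed = 9)
  expect_false(identical(ds[[1]]$counts, ds[[2]]$counts))
  # but the whole experiment is reproducible
  ds2 <- simulate_experiment(list(m, m), std_flux(),
                             measurement_condition(0.7, 450, 50), seed = 9)
  expect_identical(ds[[1]]$counts, ds2[[1]]$counts)
  expect_identical(ds[[2]]$counts, ds2[[2]]$counts)
})

test_that("noise-free simulation returns the expected counts exactly", {
  m <- benchmark_model()
  fl <- std_flux()
  cond <- measurement_condition(0.7, 450, 30)
  d <- simulate_measurement(m, fl, cond, poisson = FALSE)
  b <- neutronfi:::.bin_incident_counts(fl, cond)
  expect_equal(d$counts, b$s * model_reflectivity(b$q, m))
})

test_that("stitching pools points in ascending Q and tags their origin", {
  ds <- simulate_experiment(benchmark_model(), std_flux(), std_conds(),
                            seed = 4, stitch = TRUE)
  st <- ds$stitched[[1]]
  expect_false(is.unsorted(st$q))
  expect_length(st$q, 140)
  expect_setequal(unique(st$origin_angle), c(0.7, 2.0))
})
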