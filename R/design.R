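# internal: deterministic (noise-free) design datasets for a parameter
# set's models under a set of conditions, with all counting times scaled by
# `time_factor`. Only q and incident counts are populated, which is all the
# Fisher information needs.
.design_datasets <- function(params, flux, conds, time_factor = 1) {
  if (inherits(conds, "nr_condition")) conds <- list(conds)
  models <- params$build(params$values)
  datasets <- list()
  model_map <- integer(0)
  for (im in seq_along(models)) {
    for (cond in conds) {
      cond2 <- cond
      cond2$time <- cond$time * time_factor
      bins <- .bin_incident_counts(flux, cond2)
      keep <- !bins$empty
      d <- .new_dataset(bins$q[keep], rep(NA_integer_, sum(keep)),
                        bins$s[keep], cond2$angle, cond2$time, NULL)
      datasets <- c(datasets, list(d))
      model_map <- c(model_map, im)
    }
  }
  list(datasets = datasets, model_map = model_map)
}

#' Projection of parameter uncertainties over counting time
#'
#' Computes Fisher information uncertainties with every condition's
#' counting time multiplied by each factor in `time_factors`, then fits the
#' log-log relationship `ln eps = ln alpha + m ln tau` per parameter. The
#' information matrix is linear in counting time, so the slope m is exactly
#' -1/2: uncertainties shrink as the inverse square root of measurement
#' time. The scan is deterministic (model reflectances, no noise).
#'
#' @param params An [parameter_set()].
#' @param flux An [flux_profile()].
#' @param conds One or a list of [measurement_condition()]; their `time`
#'   fields define the base schedule.
#' @param time_factors Strictly ascending positive multipliers.
#' @return Object of class `"nr_time_scan"`: `time_factors`,
#'   `uncertainties` (factors x parameters matrix), and per-parameter
#'   `slope` and `intercept`.
#' @export
uncertainty_vs_time <- function(params, flux, conds,
                                time_factors = 10^seq(0, 3,
                                                      length.out = 10)) {
  if (any(time_factors <= 0))
    stop("time factors must be > 0")
  if (is.unsorted(time_factors, strictly = TRUE))
    stop("time_factors must be strictly ascending")
  eps <- t(vapply(time_factors, function(fac) {
    dd <- .design_datasets(params, flux, conds, time_factor = fac)
    fa <- fisher_analysis(params, dd$datasets, dd$model_map)
    parameter_uncertainties(fa$fisher)
  }, numeric(length(params$values))))
  colnames(eps) <- params$names
  fits <- apply(eps, 2, function(e) fit_loglog_slope(time_factors, e))
  structure(list(time_factors = time_factors, uncertainties = eps,
                 slope = vapply(fits, `[[`, numeric(1), "slope"),
                 intercept = vapply(fits, `[[`, numeric(1), "intercept")),
            class = "nr_time_scan")
}

#' Ordinary least-squares slope of log uncertainty versus log time
#'
#' @param times Positive times (or time factors).
#' @param uncertainties Positive uncertainties, same length.
#' @return List with `slope` and `intercept` of the regression of
#'   `log(uncertainties)` on `log(times)`.
#' @examples
#' fit_loglog_slope(c(1, 4), c(1, 0.5))  # slope -0.5
#' @export
fit_loglog_slope <- function(times, uncertainties) {
  if (length(times) < 2L)
    stop("need at least two points")
  if (any(times <= 0) || any(uncertainties <= 0))
    stop("times and uncertainties must be positive for the log transform")
  fit <- stats::lm.fit(cbind(1, log(times)), log(uncertainties))
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]))
}

#' @export
print.nr_time_scan <- function(x, ...) {
  cat(sprintf("<time scan> %d factors in [%g, %g]\n",
              length(x$time_factors), min(x$time_factors),
              max(x$time_factors)))
  print(data.frame(slope = x$slope, intercept = x$intercept,
                   row.names = colnames(x$uncertainties)), ...)
  invisible(x)
}

#' @export
plot.nr_time_scan <- function(x, ...) {
  graphics::matplot(x$time_factors, x$uncertainties, log = "xy",
                    type = "b", pch = 20, lty = 1,
                    xlab = "time factor", ylab = "FI uncertainty", ...)
  graphics::legend("bottomleft", legend = colnames(x$uncertainties),
                   col = seq_len(ncol(x$uncertainties)), lty = 1, cex = 0.7)
  invisible(x)
}

#' Fisher information versus solvent contrast
#'
#' For each candidate bulk-water contrast SLD, builds the model set
#' consisting of the already-measured contrasts plus the candidate (all
#' sharing the bilayer parameters), computes the joint Fisher information
#' over the full measurement schedule, and records the FI diagonal per
#' parameter. With an empty `prior_contrasts` this is the initial-contrast
#' choice; with `prior_contrasts = <D2O SLD>` it is the second-choice scan
#' assuming heavy water was measured first. Deterministic.
#'
#' @param bilayer A [bilayer_params()] object.
#' @param contrasts Candidate contrast SLD grid (inverse square Angstrom).
#'   Default 100 points across the pure-H2O to pure-D2O range
#'   `[-0.56e-6, 6.35e-6]`.
#' @param flux An [flux_profile()].
#' @param conds One or a list of [measurement_condition()].
#' @param prior_contrasts Numeric vector of contrast SLDs already measured.
#'   Default none.
#' @param free Character vector of free bilayer parameter names; see
#'   [bilayer_parameter_set()].
#' @return Object of class `"nr_contrast_scan"`: `contrasts`, `fi`
#'   (grid x parameters matrix of FI diagonal entries), `prior_contrasts`
#'   and the schedule used.
#' @export
contrast_scan <- function(bilayer, contrasts = NULL, flux, conds,
                          prior_contrasts = numeric(0),
                          free = c("area_per_molecule", "sio2_hydration",
                                   "headgroup_hydration",
                                   "defect_hydration",
                                   "bilayer_roughness")) {
  if (is.null(contrasts))
    contrasts <- seq(-0.56e-6, 6.35e-6, length.out = 100L)
  fi <- t(vapply(contrasts, function(cs) {
    params <- bilayer_parameter_set(bilayer, free,
                                    contrasts = c(prior_contrasts, cs))
    dd <- .design_datasets(params, flux, conds)
    fa <- fisher_analysis(params, dd$datasets, dd$model_map)
    diag(fa$fisher)
  }, numeric(length(free))))
  colnames(fi) <- free
  structure(list(contrasts = contrasts, fi = fi,
                 prior_contrasts = prior_contrasts, conditions = conds),
            class = "nr_contrast_scan")
}

#' @export
print.nr_contrast_scan <- function(x, ...) {
  cat(sprintf(
    "<contrast scan> %d contrasts in [%.3g, %.3g] /A^2, %d prior contrast(s)\n",
    length(x$contrasts), min(x$contrasts), max(x$contrasts),
    length(x$prior_contrasts)))
  best <- x$contrasts[apply(x$fi, 2, which.max)]
  print(data.frame(best_contrast = best, row.names = colnames(x$fi)), ...)
  invisible(x)
}

#' @export
plot.nr_contrast_scan <- function(x, ...) {
  graphics::matplot(x$contrasts * 1e6, x$fi, type = "l", lty = 1,
                    log = "y", xlab = "contrast SLD (1e-6 / A^2)",
                    ylab = "Fisher information", ...)
  graphics::legend("bottomright", legend = colnames(x$fi),
                   col = seq_len(ncol(x$fi)), lty = 1, cex = 0.7)
  invisible(x)
}

#' Fitting bias over repeated simulated experiments
#'
#' Simulates `n_replicates` independent experiments from the ground-truth
#' parameter values, refits each one, and reports the mean difference
#' between fitted and true values together with its standard error. Large
#' biases relative to the Fisher uncertainty indicate that the estimator
#' (not the data) limits accuracy.
#'
#' @param params An [parameter_set()] holding the ground truth.
#' @param flux An [flux_profile()].
#' @param conds One or a list of [measurement_condition()].
#' @param n_replicates Number of simulated experiments, >= 2.
#' @param seed Integer seed; replicates use independent sub-streams.
#' @param ... Passed to [fit_model()].
#' @return Object of class `"nr_bias"`: per-parameter `bias`,
#'   `standard_error`, the matrix of fitted values, and the failure count.
#'   More than 10% replicate failures aborts.
#' @export
estimate_fit_bias <- function(params, flux, conds, n_replicates = 20L,
                              seed = NULL, ...) {
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 2L) stop("n_replicates must be >= 2")
  seeds <- if (is.null(seed)) rep(list(NULL), 2L * n_replicates)
           else .with_seed(seed,
                           as.list(sample.int(.Machine$integer.max,
                                              2L * n_replicates)))
  models <- params$build(params$values)
  fitted <- matrix(NA_real_, nrow = n_replicates,
                   ncol = length(params$values),
                   dimnames = list(NULL, params$names))
  failures <- 0L
  for (k in seq_len(n_replicates)) {
    ok <- tryCatch({
      ds <- simulate_experiment(models, flux, conds,
                                seed = seeds[[2L * k - 1L]])
      fit <- fit_model(params, ds, seed = seeds[[2L * k]], ...)
      fitted[k, ] <- fit$parameters$values
      TRUE
    }, error = function(e) FALSE)
    if (!ok) failures <- failures + 1L
  }
  if (failures > 0.1 * n_replicates)
    stop(failures, " of ", n_replicates, " replicate fits failed")
  good <- stats::complete.cases(fitted)
  bias <- colMeans(fitted[good, , drop = FALSE]) - params$values
  se <- apply(fitted[good, , drop = FALSE], 2, stats::sd) / sqrt(sum(good))
  structure(list(bias = bias, standard_error = se, fitted = fitted,
                 failures = failures, truth = params$values),
            class = "nr_bias")
}

#' @export
print.nr_bias <- function(x, ...) {
  cat(sprintf("<fit bias> %d replicates, %d failures\n",
              nrow(x$fitted), x$failures))
  print(data.frame(truth = x$truth, bias = x$bias,
                   standard_error = x$standard_error,
                   row.names = names(x$bias)), ...)
  invisible(x)
}

#' Anscombe variance-stabilising transform of Poisson counts
#'
#' `2 * sqrt(N + 3/8)`, approximately unit-variance for Poisson N.
#'
#' @param counts Non-negative counts.
#' @return Transformed values.
#' @export
anscombe_transform <- function(counts) {
  if (any(counts < 0)) stop("counts must be >= 0")
  2 * sqrt(counts + 3 / 8)
}

#' Compare two reflectivity datasets by the Hotelling t-squared test
#'
#' Tests whether two measurements of the same sample (for example a
#' measured dataset and its simulated counterpart) differ beyond counting
#' noise. Counts are variance-stabilised with the Anscombe transform and
#' differenced bin by bin; each Q-bin index contributes one paired
#' observation with one component per angle dataset, and a one-sample
#' Hotelling t-squared statistic with its F-distribution p-value tests the
#' mean difference against zero. Single (stitched) datasets reduce to a
#' paired t-test.
#'
#' @param a,b Single `"nr_dataset"` objects or lists of them (one per
#'   angle). Both must share the same Q bins angle for angle.
#' @param tol Relative tolerance for the Q-bin match. Default 1e-8.
#' @return List with `t2`, `p`, and the degrees of freedom `df`.
#' @export
compare_datasets <- function(a, b, tol = 1e-8) {
  if (inherits(a, "nr_dataset")) a <- list(a)
  if (inherits(b, "nr_dataset")) b <- list(b)
  if (length(a) != length(b))
    stop("datasets have different numbers of angle sets")
  p <- length(a)
  nbins <- unique(c(vapply(a, function(d) length(d$q), integer(1)),
                    vapply(b, function(d) length(d$q), integer(1))))
  if (length(nbins) != 1L)
    stop("mismatched binning: all angle datasets must have the same ",
         "number of Q bins")
  d <- matrix(NA_real_, nrow = nbins, ncol = p)
  for (k in seq_len(p)) {
    if (max(abs(a[[k]]$q - b[[k]]$q) / pmax(abs(a[[k]]$q), 1e-300)) > tol)
      stop("mismatched binning: datasets must share the same Q bins")
    d[, k] <- anscombe_transform(a[[k]]$counts) -
      anscombe_transform(b[[k]]$counts)
  }
  n <- nbins
  if (n <= p)
    stop("need more Q bins than angle datasets for the F distribution")
  if (all(abs(d) < .Machine$double.eps))
    return(list(t2 = 0, p = 1, df = c(p, n - p)))
  xbar <- colMeans(d)
  S <- stats::cov(d)
  t2 <- as.numeric(n * crossprod(xbar, solve(S, xbar)))
  Fstat <- (n - p) / (p * (n - 1)) * t2
  pval <- stats::pf(Fstat, p, n - p, lower.tail = FALSE)
  list(t2 = t2, p = pval, df = c(p, n - p))
}
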