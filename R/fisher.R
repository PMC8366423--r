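#' Define a parameter set over one or more reflectivity models
#'
#' A parameter set binds a vector of M values (with bounds) to the fields
#' of one or more models through a builder function, so that a single
#' parameter may be shared between several models (for example one
#' area-per-molecule across all solvent contrasts). All Fisher information
#' and fitting operations act on parameter sets.
#'
#' @param names Character vector of parameter names.
#' @param values Numeric vector of current parameter values.
#' @param lower,upper Numeric bounds, elementwise `lower <= values <= upper`.
#' @param build Function taking a values vector and returning a list of
#'   [refl_model()] objects (one per experimental contrast).
#' @param fixed Logical vector; fixed parameters are never varied by
#'   [fit_model()] or [mh_sampler()]. Default all free.
#' @return Object of class `"nr_parameters"`.
#' @seealso [model_parameter_set()] for the common single-model case.
#' @export
parameter_set <- function(names, values, lower, upper, build,
                          fixed = rep(FALSE, length(values))) {
  stopifnot(is.character(names), is.numeric(values), is.function(build))
  m <- length(values)
  if (m < 1L) stop("a parameter set needs at least one parameter")
  if (length(names) != m || length(lower) != m || length(upper) != m ||
      length(fixed) != m)
    stop("names, values, lower, upper and fixed must all have length ", m)
  if (anyDuplicated(names))
    stop("parameter names must be unique (shared parameters appear once)")
  if (any(lower > upper))
    stop("every lower bound must be <= its upper bound")
  if (any(values < lower | values > upper))
    stop("parameter values must lie within their bounds")
  models <- build(values)
  if (inherits(models, "nr_model")) {
    build_one <- build
    build <- function(v) list(build_one(v))
  } else if (!is.list(models) || !all(vapply(models, inherits, logical(1),
                                             "nr_model"))) {
    stop("`build` must return an nr_model or a list of nr_model objects")
  }
  structure(list(names = names, values = as.numeric(values),
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 fixed = fixed, build = build),
            class = "nr_parameters")
}

# internal: set one dotted-path field on a model, e.g. "layer2.sld"
.set_model_field <- function(model, token, value) {
  if (grepl("^layer[0-9]+\\.", token)) {
    idx <- as.integer(sub("^layer([0-9]+)\\..*$", "\\1", token))
    field <- sub("^layer[0-9]+\\.", "", token)
    if (idx < 1L || idx > length(model$structure$layers))
      stop("no layer ", idx, " in the structure")
    if (!field %in% c("thickness", "sld", "roughness"))
      stop("unknown layer field '", field, "'")
    model$structure$layers[[idx]][[field]] <- value
  } else if (token %in% c("fronting_sld", "backing_sld",
                          "backing_roughness")) {
    model$structure[[token]] <- value
  } else if (token %in% c("scale", "background", "resolution_dq_q")) {
    model[[token]] <- value
  } else {
    stop("unknown parameter token '", token, "'")
  }
  model
}

.get_model_field <- function(model, token) {
  if (grepl("^layer[0-9]+\\.", token)) {
    idx <- as.integer(sub("^layer([0-9]+)\\..*$", "\\1", token))
    field <- sub("^layer[0-9]+\\.", "", token)
    if (idx < 1L || idx > length(model$structure$layers))
      stop("no layer ", idx, " in the structure")
    return(model$structure$layers[[idx]][[field]])
  }
  if (token %in% c("fronting_sld", "backing_sld", "backing_roughness"))
    return(model$structure[[token]])
  model[[token]]
}

#' Parameter set over the fields of a single model
#'
#' Convenience constructor naming parameters by dotted field paths:
#' `"layer<i>.thickness"`, `"layer<i>.sld"`, `"layer<i>.roughness"`,
#' `"fronting_sld"`, `"backing_sld"`, `"backing_roughness"`, `"scale"`,
#' `"background"`, `"resolution_dq_q"`. Default bounds are 25% either side
#' of the current value (the conventional uniform-prior width for
#' reflectometry fitting).
#'
#' @param model An [refl_model()].
#' @param free Character vector of field paths to treat as parameters.
#' @param lower,upper Optional explicit bounds (same length as `free`).
#' @param bound_frac Fractional half-width of the default bounds. Default
#'   0.25.
#' @return An `"nr_parameters"` object whose builder returns the modified
#'   model.
#' @examples
#' ps <- model_parameter_set(benchmark_model(),
#'                           free = c("layer2.thickness", "layer2.sld"))
#' @export
model_parameter_set <- function(model, free, lower = NULL, upper = NULL,
                                bound_frac = 0.25) {
  if (!inherits(model, "nr_model")) stop("`model` must be an nr_model")
  values <- vapply(free, .get_model_field, numeric(1), model = model)
  if (is.null(lower)) lower <- pmin(values * (1 - bound_frac),
                                    values * (1 + bound_frac))
  if (is.null(upper)) upper <- pmax(values * (1 - bound_frac),
                                    values * (1 + bound_frac))
  build <- function(v) {
    m <- model
    for (j in seq_along(free)) m <- .set_model_field(m, free[j],
                                                     unname(v[j]))
    list(m)
  }
  parameter_set(free, values, lower, upper, build)
}

# internal: normalise the datasets argument and pair each dataset with the
# model index it is described by. With one model, all datasets share it;
# with n models and k*n datasets, datasets are taken model-major.
.dataset_model_map <- function(params, datasets, model_map = NULL) {
  if (inherits(datasets, "nr_dataset")) datasets <- list(datasets)
  models <- params$build(params$values)
  nm <- length(models)
  nd <- length(datasets)
  if (is.null(model_map)) {
    if (nm == 1L) model_map <- rep(1L, nd)
    else if (nd %% nm == 0L)
      model_map <- rep(seq_len(nm), each = nd %/% nm)
    else stop("cannot infer which model describes each dataset; ",
              "supply `model_map`")
  }
  if (length(model_map) != nd)
    stop("`model_map` must have one entry per dataset")
  list(datasets = datasets, model_map = as.integer(model_map), n_models = nm)
}

# internal: concatenated model reflectivities over all datasets for given
# parameter values
.concat_reflectivity <- function(params, values, datasets, model_map) {
  models <- params$build(values)
  unlist(lapply(seq_along(datasets), function(i)
    model_reflectivity(datasets[[i]]$q, models[[model_map[i]]])))
}

#' Finite-difference Jacobian of model reflectivities
#'
#' Central difference with parameter values perturbed 0.5% either side of
#' the input value. For a parameter whose value is exactly zero the step
#' falls back to 0.5% of the bound width. Rows span the concatenated Q bins
#' of all datasets; columns are parameters.
#'
#' @param params An [parameter_set()].
#' @param datasets One `"nr_dataset"` or a list of them (only `q` is used).
#' @param model_map Optional integer vector mapping each dataset to the
#'   index of the model (from the parameter set's builder) describing it.
#' @param step_frac Relative finite-difference step. Default 0.005.
#' @return N x M numeric matrix with parameter names as column names.
#' @export
refl_jacobian <- function(params, datasets, model_map = NULL,
                          step_frac = 0.005) {
  dm <- .dataset_model_map(params, datasets, model_map)
  v <- params$values
  nq <- sum(vapply(dm$datasets, function(d) length(d$q), integer(1)))
  J <- matrix(0, nrow = nq, ncol = length(v),
              dimnames = list(NULL, params$names))
  for (j in seq_along(v)) {
    h <- if (v[j] != 0) abs(v[j]) * step_frac
         else (params$upper[j] - params$lower[j]) * step_frac
    if (h == 0)
      stop("cannot form a finite-difference step for parameter '",
           params$names[j], "' (zero value and zero bound width)")
    vp <- v; vp[j] <- v[j] + h
    vm <- v; vm[j] <- v[j] - h
    rp <- tryCatch(
      .concat_reflectivity(params, vp, dm$datasets, dm$model_map),
      error = function(e) stop("model evaluation failed while perturbing '",
                               params$names[j], "': ",
                               conditionMessage(e)))
    rm_ <- tryCatch(
      .concat_reflectivity(params, vm, dm$datasets, dm$model_map),
      error = function(e) stop("model evaluation failed while perturbing '",
                               params$names[j], "': ",
                               conditionMessage(e)))
    J[, j] <- (rp - rm_) / (2 * h)
  }
  J
}

#' Fisher information analysis of a reflectometry experiment
#'
#' Computes the Fisher information matrix `g = J' M J` for the M model
#' parameters of an experiment of N reflectivity bins, where J is the
#' finite-difference Jacobian of the model reflectances with respect to the
#' parameters and M is the diagonal matrix of expected incident counts
#' divided by model reflectances. The calculation uses model reflectances
#' (never the noisy data), so the result is a property of the experimental
#' design, independent of any particular noise realisation. Multiple
#' datasets are handled by concatenating their bins; parameters shared
#' between models appear once.
#'
#' @inheritParams refl_jacobian
#' @return Object of class `"fisher_analysis"` with elements `parameters`,
#'   `jacobian`, `fisher` (the M x M information matrix, nats per parameter
#'   unit squared), `covariance` (inverse of `fisher`, or `NULL` if
#'   numerically singular), `uncertainties` (square roots of the diagonal
#'   of the covariance) and `condition_number`.
#' @examples
#' fl <- synthetic_flux_profile()
#' cond <- measurement_condition(0.7, 450, n_points = 70)
#' d <- simulate_measurement(benchmark_model(), fl, cond, seed = 1)
#' ps <- model_parameter_set(benchmark_model(),
#'                           c("layer2.thickness", "layer2.sld"))
#' fa <- fisher_analysis(ps, d)
#' coef(fa)
#' @export
fisher_analysis <- function(params, datasets, model_map = NULL) {
  dm <- .dataset_model_map(params, datasets, model_map)
  r <- .concat_reflectivity(params, params$values, dm$datasets,
                            dm$model_map)
  if (any(r <= 0))
    stop("model reflectance is <= 0 in ", sum(r <= 0), " bin(s); a ",
         "positive background is required (M divides by model reflectance)")
  s <- unlist(lapply(dm$datasets, `[[`, "incident"))
  if (any(!is.finite(s)) || any(s < 0))
    stop("datasets must carry finite non-negative incident counts")
  J <- refl_jacobian(params, dm$datasets, dm$model_map)
  if (nrow(J) < length(params$values))
    warning("fewer reflectivity bins (", nrow(J), ") than parameters (",
            length(params$values), "); the information matrix is singular")
  g <- crossprod(J, (s / r) * J)
  g <- (g + t(g)) / 2
  dimnames(g) <- list(params$names, params$names)
  inv <- .invert_information(g, error = FALSE)
  structure(list(parameters = params, jacobian = J, fisher = g,
                 incident = s, model_reflectivity = r,
                 covariance = inv$covariance,
                 uncertainties = inv$uncertainties,
                 condition_number = inv$condition_number),
            class = "fisher_analysis")
}

# internal: invert g by eigendecomposition with a scale-invariant
# condition-number check. Parameters carry wildly different units (SLDs
# ~1e-6, thicknesses ~1e2), so conditioning is judged on the
# unit-normalised matrix D^-1/2 g D^-1/2 with D = diag(g); the raw matrix
# is then inverted through the same decomposition.
.invert_information <- function(g, error = TRUE, kappa_max = 1e10) {
  d <- diag(g)
  fail <- function(kappa, vec) {
    if (error) {
      worst <- if (is.null(vec)) "zero-information parameter"
               else paste(sprintf("%+.3f*%s", round(vec, 3), colnames(g)),
                          collapse = " ")
      stop("Fisher information matrix is singular or near-singular ",
           "(scaled condition number ", format(kappa, digits = 3),
           "); degenerate parameter combination: ", worst)
    }
    list(covariance = NULL, uncertainties = NULL, condition_number = kappa)
  }
  if (any(d <= 0)) return(fail(Inf, NULL))
  sc <- 1 / sqrt(d)
  gs <- g * tcrossprod(sc)
  e <- eigen(gs, symmetric = TRUE)
  lam <- e$values
  kappa <- if (min(lam) <= 0) Inf else max(lam) / min(lam)
  if (!is.finite(kappa) || kappa > kappa_max)
    return(fail(kappa, e$vectors[, length(lam)]))
  cov_s <- e$vectors %*% (t(e$vectors) / lam)
  cov <- cov_s * tcrossprod(sc)
  dimnames(cov) <- dimnames(g)
  list(covariance = cov, uncertainties = sqrt(diag(cov)),
       condition_number = kappa)
}

#' Parameter uncertainties from a Fisher information matrix
#'
#' The uncertainty of parameter j is the square root of the j-th diagonal
#' element of the inverse information matrix (the Cramer-Rao bound for an
#' unbiased estimator).
#'
#' @param g Symmetric positive-definite information matrix, or a
#'   `"fisher_analysis"` object.
#' @param kappa_max Condition-number threshold above which the matrix is
#'   reported singular. Default 1e10.
#' @return Named numeric vector of one-sigma uncertainties.
#' @examples
#' parameter_uncertainties(diag(c(4, 25)))  # 0.5, 0.2
#' @export
parameter_uncertainties <- function(g, kappa_max = 1e10) {
  if (inherits(g, "fisher_analysis")) g <- g$fisher
  inv <- .invert_information(g, error = TRUE, kappa_max = kappa_max)
  u <- inv$uncertainties
  if (!is.null(colnames(g))) names(u) <- colnames(g)
  u
}

#' Confidence ellipse for a parameter pair
#'
#' The boundary of the k-standard-deviation confidence region for
#' parameters (i, j): points x with
#' `(x - centre)' C^-1 (x - centre) = k^2`, where C is by default the 2x2
#' marginal block of the inverse information matrix (matching the marginal
#' views of a sampling corner plot). The conditional variant (inverse of
#' the 2x2 block of g itself) is available with `marginal = FALSE`.
#'
#' @param analysis A `"fisher_analysis"` object.
#' @param i,j Parameter indices or names, `i != j`.
#' @param k Size in standard deviations. Default 1.
#' @param n_points Number of sampled boundary points. Default 181.
#' @param marginal Use the marginal (default) or conditional covariance.
#' @return Object of class `"nr_ellipse"`: list with `centre`,
#'   `covariance` (the 2x2 C), `k`, `axes` (eigenvectors scaled by
#'   k*sqrt(eigenvalue)) and `boundary` (n x 2 closed curve).
#' @export
confidence_ellipse <- function(analysis, i, j, k = 1, n_points = 181L,
                               marginal = TRUE) {
  stopifnot(inherits(analysis, "fisher_analysis"))
  nm <- analysis$parameters$names
  if (is.character(i)) i <- match(i, nm)
  if (is.character(j)) j <- match(j, nm)
  if (is.na(i) || is.na(j) || i == j)
    stop("i and j must name two distinct parameters")
  if (marginal) {
    if (is.null(analysis$covariance))
      .invert_information(analysis$fisher, error = TRUE)  # raise the error
    C <- analysis$covariance[c(i, j), c(i, j)]
  } else {
    C <- solve(analysis$fisher[c(i, j), c(i, j)])
  }
  centre <- analysis$parameters$values[c(i, j)]
  e <- eigen(C, symmetric = TRUE)
  if (any(e$values <= 0))
    stop("marginal covariance block is not positive definite")
  axes <- e$vectors %*% diag(k * sqrt(e$values))
  t <- seq(0, 2 * pi, length.out = n_points)
  boundary <- t(centre + axes %*% rbind(cos(t), sin(t)))
  colnames(boundary) <- nm[c(i, j)]
  structure(list(centre = centre, covariance = C, k = k, axes = axes,
                 boundary = boundary, names = nm[c(i, j)]),
            class = "nr_ellipse")
}

#' Exact Kullback-Leibler divergence between Poisson count models
#'
#' The KL divergence between the joint distributions of the reflected
#' counts under two parameter vectors:
#' `sum_i lambda_i log(lambda_i / lambda'_i) - lambda_i + lambda'_i` with
#' `lambda_i = s_i r_i(xi)`. For small parameter changes this equals
#' `0.5 * d' g d` to second order, which is the oracle relationship
#' validating the information matrix.
#'
#' @param params An [parameter_set()] holding the first parameter vector.
#' @param values2 Second parameter vector (same length/order).
#' @param datasets Datasets carrying `q` and `incident`.
#' @param model_map See [refl_jacobian()].
#' @return KL divergence in nats.
#' @export
kl_divergence_counts <- function(params, values2, datasets,
                                 model_map = NULL) {
  dm <- .dataset_model_map(params, datasets, model_map)
  s <- unlist(lapply(dm$datasets, `[[`, "incident"))
  r1 <- .concat_reflectivity(params, params$values, dm$datasets,
                             dm$model_map)
  r2 <- .concat_reflectivity(params, values2, dm$datasets, dm$model_map)
  if (any(r1 <= 0) || any(r2 <= 0))
    stop("model reflectance must be > 0 at both parameter points")
  l1 <- s * r1
  l2 <- s * r2
  sum(l1 * log(l1 / l2) - l1 + l2)
}

#' Negative log-likelihood of a dataset under a model
#'
#' Gaussian likelihood of reflectivity points with known per-point
#' uncertainties: `0.5 * sum_i [((r_i - r_model_i)/dr_i)^2 +
#' log(2 pi dr_i^2)]`. Smaller is better.
#'
#' @param dataset An `"nr_dataset"` (fields `q`, `r`, `dr`).
#' @param model An [refl_model()].
#' @return Scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(dataset, model) {
  if (any(!is.finite(dataset$dr)) || any(dataset$dr <= 0))
    stop("every data point needs a positive uncertainty dr")
  rm_ <- model_reflectivity(dataset$q, model)
  0.5 * sum(((dataset$r - rm_) / dataset$dr)^2 +
              log(2 * pi * dataset$dr^2))
}

# internal: summed NLL over datasets for a values vector
.objective_nll <- function(params, values, datasets, model_map) {
  models <- params$build(values)
  sum(vapply(seq_along(datasets), function(i)
    negative_log_likelihood(datasets[[i]], models[[model_map[i]]]),
    numeric(1)))
}

#' Fit model parameters by differential evolution
#'
#' Minimises the summed negative log-likelihood over all datasets within
#' the parameter bounds using bound-constrained rand/1/bin differential
#' evolution (population-based, seed-reproducible), optionally polished
#' with bounded quasi-Newton (L-BFGS-B) from the best member. Fixed
#' parameters are held at their current values.
#'
#' @param params An [parameter_set()]; bounds must be finite for all free
#'   parameters.
#' @param datasets One or more `"nr_dataset"` objects.
#' @param model_map See [refl_jacobian()].
#' @param seed Integer seed for the optimizer's randomness.
#' @param pop_size Population size. Default `10 * n_free`, at least 20.
#' @param max_iter Maximum generations. Default 150.
#' @param tol Stop when the population objective spread falls below `tol`
#'   (relative to the best value). Default 1e-10.
#' @param F_scale,crossover DE mutation weight and crossover probability.
#' @param polish Run L-BFGS-B from the best member afterwards. Default TRUE.
#' @return Object of class `"nr_fit"`: the fitted `"nr_parameters"`, final
#'   objective, convergence flag, generations used, and the resulting
#'   `"fisher_analysis"`.
#' @export
fit_model <- function(params, datasets, model_map = NULL, seed = NULL,
                      pop_size = NULL, max_iter = 150L, tol = 1e-10,
                      F_scale = 0.8, crossover = 0.9, polish = TRUE) {
  dm <- .dataset_model_map(params, datasets, model_map)
  free <- which(!params$fixed)
  if (length(free) == 0L) {
    fit <- params
    obj <- .objective_nll(params, params$values, dm$datasets, dm$model_map)
    return(structure(list(parameters = fit, objective = obj,
                          converged = TRUE, generations = 0L),
                     class = "nr_fit"))
  }
  lo <- params$lower[free]
  hi <- params$upper[free]
  if (any(!is.finite(lo)) || any(!is.finite(hi)))
    stop("all free parameters need finite bounds for fitting")
  obj_free <- function(x) {
    v <- params$values
    v[free] <- x
    .objective_nll(params, v, dm$datasets, dm$model_map)
  }
  n <- length(free)
  if (is.null(pop_size)) pop_size <- max(20L, 10L * n)

  res <- .with_seed(seed, {
    pop <- matrix(stats::runif(pop_size * n, lo, hi), nrow = pop_size,
                  byrow = TRUE)
    pop[1, ] <- pmin(pmax(params$values[free], lo), hi)  # seed with input
    cost <- apply(pop, 1, obj_free)
    gen <- 0L
    converged <- FALSE
    while (gen < max_iter) {
      gen <- gen + 1L
      for (i in seq_len(pop_size)) {
        idx <- sample(setdiff(seq_len(pop_size), i), 3L)
        mutant <- pop[idx[1], ] + F_scale * (pop[idx[2], ] - pop[idx[3], ])
        # reflect out-of-bound components back into the box
        below <- mutant < lo; mutant[below] <- (lo + (lo - mutant))[below]
        above <- mutant > hi; mutant[above] <- (hi - (mutant - hi))[above]
        mutant <- pmin(pmax(mutant, lo), hi)
        cross <- stats::runif(n) < crossover
        cross[sample.int(n, 1L)] <- TRUE
        trial <- ifelse(cross, mutant, pop[i, ])
        tc <- obj_free(trial)
        if (tc <= cost[i]) {
          pop[i, ] <- trial
          cost[i] <- tc
        }
      }
      spread <- max(cost) - min(cost)
      if (spread <= tol * (abs(min(cost)) + tol)) {
        converged <- TRUE
        break
      }
    }
    best <- pop[which.min(cost), ]
    if (polish) {
      scale <- pmax(abs(best), (hi - lo) / 100)
      op <- stats::optim(best, obj_free, method = "L-BFGS-B",
                         lower = lo, upper = hi,
                         control = list(factr = 1e4, parscale = scale))
      if (op$value <= min(cost)) best <- op$par
    }
    list(best = best, value = obj_free(best), generations = gen,
         converged = converged)
  })

  fitted <- params
  fitted$values[free] <- res$best
  if (!res$converged && !polish)
    warning("differential evolution did not converge in ", max_iter,
            " generations; returning best-so-far values")
  structure(list(parameters = fitted, objective = res$value,
                 converged = res$converged || polish,
                 generations = res$generations),
            class = "nr_fit")
}

#' Random-walk Metropolis-Hastings posterior sampler
#'
#' A deliberately simple sampler used to cross-check Fisher information
#' uncertainties against posterior standard deviations: uniform priors on
#' the parameter bounds, Gaussian random-walk proposals, targeting the
#' Gaussian data likelihood (or a user-supplied log-likelihood).
#'
#' @param params An [parameter_set()].
#' @param datasets Datasets for the default likelihood; ignored when
#'   `log_likelihood` is given.
#' @param n_steps Total chain length. Default 1e4.
#' @param seed Integer seed.
#' @param burn_in Steps discarded from the front. Default `n_steps %/% 5`.
#' @param proposal_frac Proposal standard deviation per parameter as a
#'   fraction of its bound width. Default 0.1.
#' @param proposal_sd Optional absolute per-parameter proposal standard
#'   deviations (free parameters only); overrides `proposal_frac`.
#'   Proposal tuning affects mixing speed, never the stationary
#'   distribution.
#' @param log_likelihood Optional function(values) returning the
#'   log-likelihood; overrides `datasets`.
#' @param model_map See [refl_jacobian()].
#' @return List with `samples` (matrix, post-burn-in), `sd` (per-parameter
#'   posterior standard deviations), `mean`, and `acceptance_rate`.
#'   Acceptance rates outside `[0.05, 0.8]` trigger a warning.
#' @export
mh_sampler <- function(params, datasets = NULL, n_steps = 1e4L,
                       seed = NULL, burn_in = NULL, proposal_frac = 0.1,
                       proposal_sd = NULL, log_likelihood = NULL,
                       model_map = NULL) {
  free <- which(!params$fixed)
  if (length(free) == 0L) stop("no free parameters to sample")
  lo <- params$lower[free]
  hi <- params$upper[free]
  if (is.null(burn_in)) burn_in <- as.integer(n_steps) %/% 5L
  if (is.null(log_likelihood)) {
    if (is.null(datasets))
      stop("supply datasets or a log_likelihood function")
    dm <- .dataset_model_map(params, datasets, model_map)
    log_likelihood <- function(v)
      -.objective_nll(params, v, dm$datasets, dm$model_map)
  }
  ll_free <- function(x) {
    v <- params$values
    v[free] <- x
    log_likelihood(v)
  }
  step_sd <- if (is.null(proposal_sd)) proposal_frac * (hi - lo)
             else rep_len(proposal_sd, length(free))
  n <- length(free)
  res <- .with_seed(seed, {
    x <- pmin(pmax(params$values[free], lo), hi)
    lx <- ll_free(x)
    samples <- matrix(NA_real_, nrow = n_steps, ncol = n)
    accepted <- 0L
    for (t in seq_len(n_steps)) {
      prop <- x + stats::rnorm(n, sd = step_sd)
      if (all(prop >= lo & prop <= hi)) {  # uniform prior support
        lp <- ll_free(prop)
        if (log(stats::runif(1)) < lp - lx) {
          x <- prop
          lx <- lp
          accepted <- accepted + 1L
        }
      }
      samples[t, ] <- x
    }
    list(samples = samples, acc = accepted / n_steps)
  })
  if (res$acc < 0.05 || res$acc > 0.8)
    warning(sprintf("MH acceptance rate %.3f outside [0.05, 0.8]; adjust ",
                    res$acc), "proposal_frac")
  keep <- res$samples[(burn_in + 1L):n_steps, , drop = FALSE]
  colnames(keep) <- params$names[free]
  list(samples = keep,
       sd = apply(keep, 2, stats::sd),
       mean = colMeans(keep),
       acceptance_rate = res$acc)
}
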