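#' Instrument incident flux profile
#'
#' The incident neutron flux as a function of wavelength at a stated
#' reference angle. Intensity at other measurement angles is obtained by
#' scaling with the square of the angle ratio, reflecting collimating slits
#' that open linearly with angle.
#'
#' @param wavelengths Strictly ascending wavelength grid, Angstrom.
#' @param flux Neutrons per second per wavelength bin at the reference
#'   angle; all >= 0.
#' @param reference_angle Angle in degrees at which the profile was
#'   characterised. Default 0.3.
#' @return Object of class `"nr_flux"`.
#' @export
flux_profile <- function(wavelengths, flux, reference_angle = 0.3) {
  stopifnot(is.numeric(wavelengths), is.numeric(flux))
  if (length(wavelengths) < 2L)
    stop("a flux profile needs at least 2 wavelength points")
  if (length(wavelengths) != length(flux))
    stop("wavelengths and flux must have the same length")
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be strictly ascending")
  if (any(!is.finite(flux)) || any(flux < 0))
    stop("flux values must be finite and >= 0")
  if (reference_angle <= 0 || reference_angle >= 90)
    stop("reference_angle must be in (0, 90) degrees")
  structure(list(wavelengths = wavelengths, flux = flux,
                 reference_angle = reference_angle),
            class = "nr_flux")
}

#' Synthetic instrument flux profile
#'
#' Generates a smooth, non-negative moderator-like wavelength spectrum: a
#' Maxwellian peak `lambda^-5 exp(-2.5 (peak/lambda)^2)` plus a `1/lambda`
#' epithermal tail (the standard two-component moderator description,
#' which keeps usable flux across the whole time-of-flight band),
#' normalised so the summed bin-integrated flux equals `total_flux`. This
#' deterministic profile stands in for a measured instrument spectrum in
#' simulations.
#'
#' @param lambda_min,lambda_max Wavelength range, Angstrom.
#' @param n Number of wavelength points. Default 1000.
#' @param peak_wavelength Wavelength of maximum Maxwellian flux, Angstrom.
#'   Default 2.5.
#' @param total_flux Integrated flux, neutrons per second at the reference
#'   angle. Default 1e8 (a realistic white-beam reflectometer level, and
#'   high enough that standard two-angle schedules leave no empty-count
#'   bins).
#' @param epithermal_fraction Fraction of the integrated flux carried by
#'   the `1/lambda` tail. Default 0.1.
#' @param reference_angle Degrees; see [flux_profile()]. Default 0.3.
#' @return An [flux_profile()] object.
#' @examples
#' fl <- synthetic_flux_profile(0.5, 12)
#' sum(fl$flux)  # = 1e8
#' @export
synthetic_flux_profile <- function(lambda_min = 0.5, lambda_max = 12,
                                   n = 1000L, peak_wavelength = 2.5,
                                   total_flux = 1e8,
                                   epithermal_fraction = 0.1,
                                   reference_angle = 0.3) {
  if (lambda_min >= lambda_max)
    stop("lambda_min must be < lambda_max")
  if (lambda_min <= 0)
    stop("wavelengths must be positive")
  if (epithermal_fraction < 0 || epithermal_fraction > 1)
    stop("epithermal_fraction must be in [0, 1]")
  lam <- seq(lambda_min, lambda_max, length.out = as.integer(n))
  maxwell <- lam^-5 * exp(-2.5 * (peak_wavelength / lam)^2)
  epi <- 1 / lam
  shape <- (1 - epithermal_fraction) * maxwell / sum(maxwell) +
    epithermal_fraction * epi / sum(epi)
  flux <- shape * (total_flux / sum(shape))
  flux_profile(lam, flux, reference_angle = reference_angle)
}

#' One measurement condition (angle, time, binning)
#'
#' @param angle Measurement angle theta in degrees, in (0, 90).
#' @param time Counting time tau in seconds, > 0.
#' @param n_points Number of Q bins (ignored if `q_bin_centres` given).
#' @param q_bin_centres Optional explicit Q bin centres, inverse Angstrom,
#'   strictly ascending.
#' @return Object of class `"nr_condition"`.
#' @export
measurement_condition <- function(angle, time, n_points = 70L,
                                  q_bin_centres = NULL) {
  if (!is.finite(angle) || angle <= 0 || angle >= 90)
    stop("angle must be in (0, 90) degrees")
  if (!is.finite(time) || time <= 0)
    stop("time must be > 0 seconds")
  n_points <- as.integer(n_points)
  if (is.null(q_bin_centres) && n_points < 1L)
    stop("n_points must be >= 1")
  if (!is.null(q_bin_centres) &&
      is.unsorted(q_bin_centres, strictly = TRUE))
    stop("q_bin_centres must be strictly ascending")
  structure(list(angle = angle, time = time, n_points = n_points,
                 q_bin_centres = q_bin_centres),
            class = "nr_condition")
}

#' Momentum transfer from wavelength and angle
#'
#' `Q = 4 pi sin(theta) / lambda`.
#'
#' @param wavelength Wavelength(s), Angstrom, > 0.
#' @param angle Measurement angle, degrees.
#' @return Momentum transfer, inverse Angstrom.
#' @examples
#' q_from_wavelength(2 * pi, 30)  # 1.0
#' @export
q_from_wavelength <- function(wavelength, angle) {
  if (any(wavelength <= 0))
    stop("wavelength must be > 0")
  4 * pi * sin(angle * pi / 180) / wavelength
}

#' Geometrically spaced Q bins
#'
#' Bin edges form a geometric progression from `q_min` to `q_max`; the
#' centre of each bin is the geometric mean of its edges (arithmetic mean
#' available via `centre`).
#'
#' @param q_min,q_max Positive range, `q_min < q_max`.
#' @param n_bins Number of bins, >= 1.
#' @param centre `"geometric"` (default) or `"arithmetic"` bin centres.
#' @return List with `edges` (length `n_bins + 1`) and `centres`
#'   (length `n_bins`).
#' @examples
#' geometric_q_bins(0.01, 0.04, 2)  # edges 0.01, 0.02, 0.04
#' @export
geometric_q_bins <- function(q_min, q_max, n_bins,
                             centre = c("geometric", "arithmetic")) {
  centre <- match.arg(centre)
  if (!is.finite(q_min) || !is.finite(q_max) || q_min <= 0 || q_min >= q_max)
    stop("need 0 < q_min < q_max")
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L)
    stop("n_bins must be >= 1")
  edges <- exp(seq(log(q_min), log(q_max), length.out = n_bins + 1L))
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  centres <- if (centre == "geometric") sqrt(lo * hi) else (lo + hi) / 2
  list(edges = edges, centres = centres)
}

#' Angle-squared intensity scaling factor
#'
#' Both collimating slits open linearly with the measurement angle, so the
#' incident intensity scales as the square of the angle relative to the
#' angle at which the flux profile was characterised.
#'
#' @param angle Measurement angle, degrees, > 0.
#' @param reference_angle Reference angle, degrees, > 0.
#' @return `(angle / reference_angle)^2`.
#' @export
angle_intensity_factor <- function(angle, reference_angle) {
  if (angle <= 0 || reference_angle <= 0)
    stop("angles must be > 0")
  (angle / reference_angle)^2
}

# internal: run `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards. seed = NULL uses the current
# stream without touching it.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# internal: deterministic per-bin expected incident counts for one
# condition. Returns q centres, s_i = mu_i * tau (after angle scaling) and
# a logical flag for empty bins.
.bin_incident_counts <- function(flux, cond) {
  qs <- q_from_wavelength(flux$wavelengths, cond$angle)
  fac <- angle_intensity_factor(cond$angle, flux$reference_angle)
  if (!is.null(cond$q_bin_centres)) {
    centres <- cond$q_bin_centres
    # edges midway (geometrically) between supplied centres
    inner <- sqrt(centres[-1] * centres[-length(centres)])
    edges <- c(centres[1]^2 / inner[1],
               inner,
               centres[length(centres)]^2 / inner[length(inner)])
    if (length(centres) == 1L) edges <- range(qs)
  } else {
    pos <- qs > 0
    if (!any(pos) || sum(flux$flux[pos]) == 0)
      return(list(q = numeric(0), s = numeric(0), empty = logical(0)))
    b <- geometric_q_bins(min(qs[pos]), max(qs), cond$n_points)
    edges <- b$edges
    centres <- b$centres
  }
  # each wavelength's flux is assigned wholly to the bin containing its Q
  idx <- findInterval(qs, edges, rightmost.closed = TRUE,
                      all.inside = FALSE)
  inside <- idx >= 1L & idx <= length(centres)
  mu <- vapply(seq_along(centres),
               function(i) sum(flux$flux[inside & idx == i]),
               numeric(1))
  s <- mu * cond$time * fac
  list(q = centres, s = s, empty = s <= 0)
}

#' Simulate one reflectivity measurement
#'
#' Histograms the instrument flux into Q bins for the given angle, scales
#' by counting time and the angle-squared intensity factor to obtain the
#' expected incident neutrons per bin `s_i`, evaluates the model
#' reflectivity at the bin centres and draws the reflected counts from a
#' Poisson distribution with mean `s_i * r_i`. Reflectivity and its
#' uncertainty are the noisy counts and their square root divided by `s_i`.
#'
#' @param model An [refl_model()].
#' @param flux An [flux_profile()].
#' @param cond A [measurement_condition()].
#' @param seed Optional integer seed; the same seed reproduces the dataset
#'   bit for bit. The caller's RNG state is left untouched.
#' @param poisson If `FALSE`, skip the Poisson draw and set the counts to
#'   their expectation `s_i r_i` (a noise-free dataset, useful for
#'   estimator self-consistency checks). Default `TRUE`.
#' @return Object of class `"nr_dataset"`: a list with `q`, `counts`,
#'   `incident` (`s_i`), `r`, `dr`, and the `angle`, `time`, `seed` used.
#'   Bins receiving no incident flux are dropped with a warning.
#' @export
simulate_measurement <- function(model, flux, cond, seed = NULL,
                                 poisson = TRUE) {
  if (!inherits(model, "nr_model")) stop("`model` must be an nr_model")
  if (!inherits(flux, "nr_flux")) stop("`flux` must be an nr_flux")
  if (!inherits(cond, "nr_condition"))
    stop("`cond` must be an nr_condition")
  bins <- .bin_incident_counts(flux, cond)
  if (length(bins$q) == 0L || all(bins$empty)) {
    warning("no incident flux reaches any Q bin; returning empty dataset")
    return(.new_dataset(numeric(0), integer(0), numeric(0),
                        cond$angle, cond$time, seed))
  }
  if (any(bins$empty))
    warning(sum(bins$empty), " empty Q bin(s) dropped (no incident flux)")
  keep <- !bins$empty
  q <- bins$q[keep]
  s <- bins$s[keep]
  r_model <- model_reflectivity(q, model)
  counts <- if (poisson)
    .with_seed(seed, stats::rpois(length(q), lambda = s * r_model))
  else s * r_model
  .new_dataset(q, counts, s, cond$angle, cond$time, seed)
}

.new_dataset <- function(q, counts, incident, angle, time, seed) {
  r <- ifelse(incident > 0, counts / incident, NA_real_)
  dr <- ifelse(incident > 0, sqrt(counts) / incident, NA_real_)
  structure(list(q = q, counts = counts, incident = incident,
                 r = r, dr = dr, angle = angle, time = time,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "nr_dataset")
}

#' Simulate a multi-model, multi-angle experiment
#'
#' Repeats [simulate_measurement()] for every combination of model (one per
#' experimental contrast) and measurement condition. A single experiment
#' seed deterministically spawns an independent sub-stream for each
#' dataset, so two identical models still receive independent noise.
#'
#' @param models A single [refl_model()] or list of them (one per
#'   contrast).
#' @param flux An [flux_profile()].
#' @param conds A single [measurement_condition()] or list of them.
#' @param seed Optional integer experiment seed.
#' @param stitch If `TRUE`, additionally return each model's per-angle
#'   datasets merged into one ascending-Q dataset (overlapping Q regions
#'   kept, tagged by angle of origin).
#' @param poisson See [simulate_measurement()].
#' @return List of `"nr_dataset"` objects, one per (model, condition) in
#'   model-major order; if `stitch = TRUE`, a list with elements
#'   `datasets` and `stitched`.
#' @export
simulate_experiment <- function(models, flux, conds, seed = NULL,
                                stitch = FALSE, poisson = TRUE) {
  if (inherits(models, "nr_model")) models <- list(models)
  if (inherits(conds, "nr_condition")) conds <- list(conds)
  if (length(models) < 1L || length(conds) < 1L)
    stop("need at least one model and one condition")
  n <- length(models) * length(conds)
  subseeds <- if (is.null(seed)) rep(list(NULL), n)
              else .with_seed(seed, as.list(sample.int(.Machine$integer.max, n)))
  out <- vector("list", n)
  k <- 1L
  for (im in seq_along(models)) {
    for (ic in seq_along(conds)) {
      out[[k]] <- simulate_measurement(models[[im]], flux, conds[[ic]],
                                       seed = subseeds[[k]],
                                       poisson = poisson)
      k <- k + 1L
    }
  }
  if (!stitch) return(out)
  nc <- length(conds)
  stitched <- lapply(seq_along(models), function(im) {
    parts <- out[(im - 1L) * nc + seq_len(nc)]
    stitch_datasets(parts)
  })
  list(datasets = out, stitched = stitched)
}

#' Merge per-angle datasets into one ascending-Q view
#'
#' Convenience view only: points from all datasets are pooled and sorted by
#' Q, keeping duplicated Q regions and recording the angle of origin of
#' every point. Fisher information computations always use the per-angle
#' datasets' incident counts, never a stitched average.
#'
#' @param datasets List of `"nr_dataset"` objects.
#' @return One `"nr_dataset"` with an extra `origin_angle` field.
#' @export
stitch_datasets <- function(datasets) {
  q <- unlist(lapply(datasets, `[[`, "q"))
  o <- order(q)
  ds <- .new_dataset(
    q[o],
    unlist(lapply(datasets, `[[`, "counts"))[o],
    unlist(lapply(datasets, `[[`, "incident"))[o],
    angle = NA_real_, time = NA_real_, seed = NULL
  )
  ds$origin_angle <- unlist(lapply(datasets, function(d)
    rep(d$angle, length(d$q))))[o]
  ds
}

#' @export
print.nr_dataset <- function(x, ...) {
  cat(sprintf(
    "<reflectivity dataset> %d points, Q in [%.4g, %.4g] /A, angle %s deg, time %s s\n",
    length(x$q),
    if (length(x$q)) min(x$q) else NA, if (length(x$q)) max(x$q) else NA,
    format(x$angle), format(x$time)))
  invisible(x)
}

#' @export
plot.nr_dataset <- function(x, ...) {
  graphics::plot(x$q, x$r, log = "y", xlab = "Q (1/A)",
                 ylab = "Reflectivity", pch = 20, ...)
  graphics::arrows(x$q, pmax(x$r - x$dr, .Machine$double.xmin),
                   x$q, x$r + x$dr,
                   length = 0.02, angle = 90, code = 3)
  invisible(x)
}
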