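#' @useDynLib neutronfi, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Define a single layer of a stratified sample
#'
#' A layer is described by its thickness, its scattering length density
#' (SLD) and the Gaussian (Nevot-Croce) roughness of the interface between
#' this layer and the medium above it (towards the fronting).
#'
#' @param thickness Layer thickness in Angstrom; must be > 0.
#' @param sld Real scattering length density in inverse square Angstrom
#'   (true units, e.g. `6.385e-6`). Absorption (complex SLD) is not
#'   supported.
#' @param roughness Gaussian width in Angstrom of the top interface of the
#'   layer; must be >= 0. Default 0.
#' @return An object of class `"nr_layer"`.
#' @examples
#' layer(297.9, 6.385e-6, 3.5)
#' @export
layer <- function(thickness, sld, roughness = 0) {
  stopifnot(is.numeric(thickness), length(thickness) == 1L,
            is.numeric(sld), length(sld) == 1L,
            is.numeric(roughness), length(roughness) == 1L)
  if (!is.finite(thickness) || thickness <= 0)
    stop("layer thickness must be finite and > 0 (got ", thickness, ")")
  if (is.complex(sld))
    stop("complex SLD (absorption) is not supported")
  if (!is.finite(sld))
    stop("layer SLD must be finite")
  if (!is.finite(roughness) || roughness < 0)
    stop("layer roughness must be finite and >= 0 (got ", roughness, ")")
  structure(list(thickness = thickness, sld = sld, roughness = roughness),
            class = "nr_layer")
}

#' Define a stratified sample structure
#'
#' Layers are ordered fronting-first throughout the package: the first
#' element of `layers` is adjacent to the fronting (incident) medium and the
#' last is adjacent to the backing medium. The list may be empty, describing
#' a bare fronting/backing interface.
#'
#' @param fronting_sld SLD of the semi-infinite medium the beam arrives
#'   through, in inverse square Angstrom.
#' @param layers List of [layer()] objects, fronting to backing. May be
#'   empty.
#' @param backing_sld SLD of the semi-infinite backing medium.
#' @param backing_roughness Gaussian roughness in Angstrom of the interface
#'   between the deepest layer (or the fronting, if no layers) and the
#'   backing.
#' @return An object of class `"nr_structure"`.
#' @examples
#' refl_structure(
#'   fronting_sld = 0,
#'   layers = list(layer(790.7, 1.795e-6, 24.5), layer(297.9, 6.385e-6, 3.5)),
#'   backing_sld = 3.354e-6, backing_roughness = 12.9
#' )
#' @export
refl_structure <- function(fronting_sld, layers = list(), backing_sld,
                           backing_roughness = 0) {
  stopifnot(is.numeric(fronting_sld), length(fronting_sld) == 1L,
            is.numeric(backing_sld), length(backing_sld) == 1L,
            is.list(layers))
  if (is.complex(fronting_sld) || is.complex(backing_sld))
    stop("complex SLD (absorption) is not supported")
  if (!is.finite(backing_roughness) || backing_roughness < 0)
    stop("backing_roughness must be finite and >= 0")
  for (ly in layers) {
    if (!inherits(ly, "nr_layer"))
      stop("every element of `layers` must be created with layer()")
  }
  structure(list(fronting_sld = fronting_sld, layers = layers,
                 backing_sld = backing_sld,
                 backing_roughness = backing_roughness),
            class = "nr_structure")
}

# internal: flatten a structure into the vectors the kernel expects
.structure_arrays <- function(struct) {
  nl <- length(struct$layers)
  sld <- c(struct$fronting_sld,
           vapply(struct$layers, function(x) x$sld, numeric(1)),
           struct$backing_sld)
  thickness <- c(0, vapply(struct$layers, function(x) x$thickness,
                           numeric(1)), 0)
  # interface i--(i+1) carries the roughness of the lower medium's top
  # interface; the final interface carries backing_roughness
  roughness <- c(vapply(struct$layers, function(x) x$roughness, numeric(1)),
                 struct$backing_roughness)
  list(sld = sld, thickness = thickness, roughness = roughness, n = nl)
}

#' Unsmeared specular reflectivity by the Abeles matrix formalism
#'
#' Computes the raw reflectance r(Q) of a stratified medium using the
#' characteristic-matrix recursion, with Nevot-Croce Gaussian roughness
#' damping applied to each interfacial Fresnel coefficient. The result is
#' unscaled and contains no background or resolution smearing.
#'
#' @param q_values Momentum transfer values in inverse Angstrom; all must be
#'   finite and >= 0.
#' @param struct An [refl_structure()] object.
#' @return Numeric vector of reflectivities in `[0, 1]`, one per Q.
#' @examples
#' s <- refl_structure(0, list(), backing_sld = 2.047e-6)
#' abeles_reflectivity(c(0.005, 0.05, 0.2), s)
#' @export
abeles_reflectivity <- function(q_values, struct) {
  if (!inherits(struct, "nr_structure"))
    stop("`struct` must be an nr_structure")
  if (!is.numeric(q_values) || anyNA(q_values) || any(!is.finite(q_values)))
    stop("q_values must be finite numeric values")
  if (any(q_values < 0))
    stop("q_values must be >= 0 (negative momentum transfer supplied)")
  a <- .structure_arrays(struct)
  .abeles_cpp(as.numeric(q_values), a$sld, a$thickness, a$roughness)
}

# FWHM of a Gaussian = 2 sqrt(2 ln 2) sigma
.FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Apply Gaussian dQ/Q resolution smearing
#'
#' Each reflectivity point becomes the Gaussian-weighted average of the
#' unsmeared model over a kernel whose full width at half-maximum is
#' `resolution_dq_q * Q`. The average is evaluated by fixed-node
#' quadrature on equally spaced nodes spanning +/- 3.5 standard
#' deviations. A zero resolution returns the unsmeared values unchanged.
#' The default node count keeps the quadrature within about one part in
#' 1e4 of a dense (2001-node) convolution for typical fringed curves.
#'
#' @param q_values Momentum transfer grid, inverse Angstrom.
#' @param r_fun Function taking a numeric Q vector and returning the
#'   unsmeared reflectivity at those points.
#' @param resolution_dq_q Fractional FWHM of the Gaussian dQ/Q kernel
#'   (e.g. 0.025 for 2.5%); must be >= 0.
#' @param n_nodes Number of quadrature nodes (>= 17; default 101).
#' @return Numeric vector of smeared reflectivities.
#' @export
smear_resolution <- function(q_values, r_fun, resolution_dq_q,
                             n_nodes = 101L) {
  stopifnot(is.function(r_fun), is.numeric(resolution_dq_q),
            length(resolution_dq_q) == 1L)
  if (resolution_dq_q < 0)
    stop("resolution_dq_q must be >= 0")
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 17L)
    stop("n_nodes must be at least 17 for adequate kernel coverage")
  if (resolution_dq_q == 0)
    return(r_fun(q_values))
  z <- seq(-3.5, 3.5, length.out = n_nodes)
  w <- stats::dnorm(z)
  w <- w / sum(w)
  sigma <- resolution_dq_q * q_values * .FWHM_TO_SIGMA
  # node grid: one row per Q point, columns are kernel offsets
  qs <- outer(sigma, z) + q_values
  qs[qs < 0] <- 0
  rv <- r_fun(as.numeric(qs))
  dim(rv) <- dim(qs)
  as.numeric(rv %*% w)
}

#' Define a reflectivity model
#'
#' Combines a sample structure with the experimental scale factor, additive
#' instrument background and fractional Gaussian dQ/Q resolution.
#'
#' @param struct An [refl_structure()] object.
#' @param scale Dimensionless experimental scale factor, > 0.
#' @param background Additive background in reflectivity units, >= 0.
#' @param resolution_dq_q Fractional FWHM of the Gaussian dQ/Q resolution
#'   kernel, >= 0 (e.g. 0.025 for 2.5% dQ/Q).
#' @return Object of class `"nr_model"`.
#' @export
refl_model <- function(struct, scale = 1, background = 0,
                       resolution_dq_q = 0) {
  if (!inherits(struct, "nr_structure"))
    stop("`struct` must be an nr_structure")
  if (!is.finite(scale) || scale <= 0)
    stop("scale must be finite and > 0")
  if (!is.finite(background) || background < 0)
    stop("background must be finite and >= 0")
  if (!is.finite(resolution_dq_q) || resolution_dq_q < 0)
    stop("resolution_dq_q must be finite and >= 0")
  structure(list(structure = struct, scale = scale, background = background,
                 resolution_dq_q = resolution_dq_q),
            class = "nr_model")
}

#' Model reflectivity with scale, background and resolution
#'
#' The quantity entering both experiment simulation and the Fisher
#' information: `scale * smear(abeles(Q)) + background`. The background is
#' additive and not multiplied by the scale factor, since it represents
#' detector noise independent of the illumination normalisation.
#'
#' @param q_values Momentum transfer grid, inverse Angstrom.
#' @param model An [refl_model()] object.
#' @return Numeric vector of model reflectivities.
#' @examples
#' m <- benchmark_model()
#' model_reflectivity(c(0.01, 0.05, 0.2), m)
#' @export
model_reflectivity <- function(q_values, model) {
  if (!inherits(model, "nr_model"))
    stop("`model` must be an nr_model")
  smeared <- smear_resolution(
    q_values, function(q) abeles_reflectivity(q, model$structure),
    model$resolution_dq_q
  )
  model$scale * smeared + model$background
}

#' @export
print.nr_layer <- function(x, ...) {
  cat(sprintf("<layer> %8.2f A thick, SLD %.4g /A^2, roughness %.2f A\n",
              x$thickness, x$sld, x$roughness))
  invisible(x)
}

#' @export
print.nr_structure <- function(x, ...) {
  cat(sprintf("<structure> fronting SLD %.4g /A^2\n", x$fronting_sld))
  for (ly in x$layers)
    cat(sprintf("  layer: %8.2f A, SLD %.4g /A^2, roughness %.2f A\n",
                ly$thickness, ly$sld, ly$roughness))
  cat(sprintf("  backing SLD %.4g /A^2, roughness %.2f A\n",
              x$backing_sld, x$backing_roughness))
  invisible(x)
}

#' @export
print.nr_model <- function(x, ...) {
  print(x$structure)
  cat(sprintf("  scale %.4g, background %.3g, resolution %.2f%% dQ/Q\n",
              x$scale, x$background, 100 * x$resolution_dq_q))
  invisible(x)
}
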