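#' Supported lipid bilayer parameterised by area per molecule and contrast
#'
#' Describes a DMPC-style bilayer on a silicon block: native SiO2 layer,
#' inner headgroups, merged tailgroups, outer headgroups, bulk water
#' backing. The model is parameterised by the area per molecule rather than
#' volume fractions: with fixed component molecular volumes, leaflet
#' thicknesses follow as volume / area, so surface area changes are
#' inversely proportional to layer thicknesses. Water enters the lipid
#' layers in two ways, through defects across the head/tail surfaces and as
#' water bound to the hydrophilic headgroups; only the summed water volume
#' fraction affects a layer's SLD. The bulk-water contrast SLD appears as
#' the backing and inside every hydrated layer, which is what makes
#' contrast-variation design possible.
#'
#' Component volumes and scattering lengths default to conventional
#' literature values for DMPC and are fixed (not fittable); they are inputs
#' of the parameterisation, not ground truth.
#'
#' @param si_sld Fronting (silicon) SLD, inverse square Angstrom.
#' @param sio2_sld Dry SiO2 SLD.
#' @param sio2_thickness,sio2_hydration,sio2_roughness Native oxide layer:
#'   thickness (A), water volume fraction in `[0, 1]`, and the roughness of
#'   the Si/SiO2 interface (A).
#' @param area_per_molecule Interfacial area per lipid molecule, square
#'   Angstrom.
#' @param headgroup_volume,tailgroup_volume Molecular volumes per lipid,
#'   cubic Angstrom (fixed).
#' @param headgroup_sl,tailgroup_sl Coherent scattering lengths per lipid
#'   component, Angstrom (fixed).
#' @param headgroup_hydration Volume fraction of bound water in the
#'   headgroup layers.
#' @param defect_hydration Volume fraction of water in defects, applied to
#'   both headgroup and tailgroup layers.
#' @param bilayer_roughness Conformal roughness of all lipid interfaces
#'   (A).
#' @param contrast_sld Bulk water SLD (the backing medium).
#' @return Object of class `"nr_bilayer"`.
#' @examples
#' bp <- bilayer_params(contrast_sld = 6.35e-6)
#' bilayer_structure(bp)
#' @export
bilayer_params <- function(si_sld = 2.073e-6,
                           sio2_sld = 3.47e-6,
                           sio2_thickness = 14.7,
                           sio2_hydration = 0.245,
                           sio2_roughness = 3.0,
                           area_per_molecule = 57.0,
                           headgroup_volume = 320.9,
                           tailgroup_volume = 780.1,
                           headgroup_sl = 6.01e-4,
                           tailgroup_sl = -2.91e-4,
                           headgroup_hydration = 0.27,
                           defect_hydration = 0.12,
                           bilayer_roughness = 4.0,
                           contrast_sld = 6.35e-6) {
  p <- list(si_sld = si_sld, sio2_sld = sio2_sld,
            sio2_thickness = sio2_thickness,
            sio2_hydration = sio2_hydration,
            sio2_roughness = sio2_roughness,
            area_per_molecule = area_per_molecule,
            headgroup_volume = headgroup_volume,
            tailgroup_volume = tailgroup_volume,
            headgroup_sl = headgroup_sl,
            tailgroup_sl = tailgroup_sl,
            headgroup_hydration = headgroup_hydration,
            defect_hydration = defect_hydration,
            bilayer_roughness = bilayer_roughness,
            contrast_sld = contrast_sld)
  for (f in c("sio2_hydration", "headgroup_hydration", "defect_hydration"))
    if (p[[f]] < 0 || p[[f]] > 1)
      stop(f, " must be a fraction in [0, 1]")
  for (f in c("sio2_thickness", "area_per_molecule", "headgroup_volume",
              "tailgroup_volume"))
    if (p[[f]] <= 0)
      stop(f, " must be > 0")
  if (p$headgroup_hydration + p$defect_hydration > 1)
    stop("total headgroup water fraction (bound + defect) exceeds 1")
  if (p$sio2_roughness < 0 || p$bilayer_roughness < 0)
    stop("roughnesses must be >= 0")
  class(p) <- "nr_bilayer"
  p
}

# fixed molecular quantities: never fittable under the constant-volume
# assumption
.BILAYER_FIXED <- c("headgroup_volume", "tailgroup_volume",
                    "headgroup_sl", "tailgroup_sl", "si_sld")

#' Leaflet thicknesses implied by the fixed volumes
#'
#' `t = V / area_per_molecule` for headgroup and (single-leaflet)
#' tailgroup.
#'
#' @param params A [bilayer_params()] object.
#' @return Named vector with `headgroup` and `tailgroup` thicknesses (A).
#' @export
bilayer_thicknesses <- function(params) {
  c(headgroup = unname(params$headgroup_volume / params$area_per_molecule),
    tailgroup = unname(params$tailgroup_volume / params$area_per_molecule))
}

#' Build the layer structure of a supported bilayer at one contrast
#'
#' Stack, fronting to backing: Si | hydrated SiO2 | inner headgroup |
#' tailgroups (both leaflets merged) | outer headgroup | bulk water. Each
#' hydrated layer's SLD is the volume-fraction mixture
#' `(1 - phi_w) * (b / V) + phi_w * contrast_sld`, where `phi_w` sums the
#' defect water and, for headgroups, the bound water. Headgroup thickness
#' is `V_h / APM`; the merged tail layer is `2 V_t / APM` (`split_tails`
#' gives two leaflet layers of `V_t / APM` each).
#'
#' @param params A [bilayer_params()] object.
#' @param split_tails Model the two tail leaflets as separate layers.
#'   Default FALSE.
#' @return An [refl_structure()].
#' @export
bilayer_structure <- function(params, split_tails = FALSE) {
  if (!inherits(params, "nr_bilayer"))
    stop("`params` must be created with bilayer_params()")
  th <- bilayer_thicknesses(params)
  if (any(th <= 0))
    stop("derived leaflet thickness <= 0")
  head_dry <- params$headgroup_sl / params$headgroup_volume
  tail_dry <- params$tailgroup_sl / params$tailgroup_volume
  head_w <- params$headgroup_hydration + params$defect_hydration
  tail_w <- params$defect_hydration
  mix <- function(dry, phi) (1 - phi) * dry + phi * params$contrast_sld
  sio2 <- layer(params$sio2_thickness,
                mix(params$sio2_sld, params$sio2_hydration),
                params$sio2_roughness)
  head_in <- layer(th["headgroup"], mix(head_dry, head_w),
                   params$bilayer_roughness)
  head_out <- layer(th["headgroup"], mix(head_dry, head_w),
                    params$bilayer_roughness)
  tails <- if (split_tails) {
    list(layer(th["tailgroup"], mix(tail_dry, tail_w),
               params$bilayer_roughness),
         layer(th["tailgroup"], mix(tail_dry, tail_w),
               params$bilayer_roughness))
  } else {
    list(layer(2 * th["tailgroup"], mix(tail_dry, tail_w),
               params$bilayer_roughness))
  }
  refl_structure(
    fronting_sld = params$si_sld,
    layers = c(list(sio2, head_in), tails, list(head_out)),
    backing_sld = params$contrast_sld,
    backing_roughness = params$bilayer_roughness
  )
}

#' Bulk water contrast SLD from the D2O volume fraction
#'
#' Linear mixing between pure H2O (-0.56e-6) and pure D2O (6.35e-6)
#' scattering length densities.
#'
#' @param x D2O volume fraction in `[0, 1]`.
#' @return Contrast SLD, inverse square Angstrom.
#' @examples
#' contrast_sld_from_d2o_fraction(c(0, 0.5, 1))
#' @export
contrast_sld_from_d2o_fraction <- function(x) {
  if (any(x < 0 | x > 1))
    stop("D2O fraction must be in [0, 1]")
  (1 - x) * -0.56e-6 + x * 6.35e-6
}

#' Shared parameter set across solvent contrasts of a bilayer
#'
#' Builds an [parameter_set()] whose builder emits one reflectivity model
#' per contrast SLD, all sharing the freed bilayer parameters. This is the
#' joint multi-contrast object on which Fisher information additivity over
#' independent datasets operates. The fixed molecular volumes and
#' scattering lengths (and the substrate SLD) cannot be freed.
#'
#' @param params A [bilayer_params()] object.
#' @param free Character vector of bilayer field names to treat as
#'   parameters (non-empty).
#' @param contrasts Numeric vector of bulk-water contrast SLDs, one model
#'   per entry. Defaults to the single contrast stored in `params`.
#' @param scale,background,resolution_dq_q Instrument terms applied to
#'   every contrast's model.
#' @param bound_frac Fractional half-width of default bounds; hydration
#'   bounds are clipped to `[0, 1]`. Default 0.25.
#' @param split_tails Passed to [bilayer_structure()].
#' @return An `"nr_parameters"` object.
#' @examples
#' bp <- bilayer_params()
#' ps <- bilayer_parameter_set(bp, free = c("area_per_molecule"),
#'                             contrasts = contrast_sld_from_d2o_fraction(c(0, 1)))
#' @export
bilayer_parameter_set <- function(params, free, contrasts = NULL,
                                  scale = 1, background = 1e-6,
                                  resolution_dq_q = 0.02,
                                  bound_frac = 0.25,
                                  split_tails = FALSE) {
  if (!inherits(params, "nr_bilayer"))
    stop("`params` must be created with bilayer_params()")
  if (length(free) == 0L)
    stop("at least one bilayer parameter must be freed")
  bad <- intersect(free, .BILAYER_FIXED)
  if (length(bad))
    stop("cannot free fixed field(s) ", paste(bad, collapse = ", "),
         ": molecular volumes and scattering lengths are assumed known ",
         "and constant in this parameterisation")
  unknown <- setdiff(free, names(params))
  if (length(unknown))
    stop("unknown bilayer field(s): ", paste(unknown, collapse = ", "))
  if (is.null(contrasts)) contrasts <- params$contrast_sld
  values <- vapply(free, function(f) params[[f]], numeric(1))
  lower <- pmin(values * (1 - bound_frac), values * (1 + bound_frac))
  upper <- pmax(values * (1 - bound_frac), values * (1 + bound_frac))
  hyd <- grepl("hydration", free)
  lower[hyd] <- pmax(lower[hyd], 0)
  upper[hyd] <- pmin(upper[hyd], 1)
  build <- function(v) {
    p <- params
    for (j in seq_along(free)) p[[free[j]]] <- unname(v[j])
    lapply(contrasts, function(cs) {
      p$contrast_sld <- cs
      refl_model(bilayer_structure(p, split_tails = split_tails),
                 scale = scale, background = background,
                 resolution_dq_q = resolution_dq_q)
    })
  }
  parameter_set(free, values, lower, upper, build)
}

#' @export
print.nr_bilayer <- function(x, ...) {
  th <- bilayer_thicknesses(x)
  cat("<supported bilayer>\n")
  cat(sprintf("  SiO2: %.1f A, hydration %.2f, roughness %.1f A\n",
              x$sio2_thickness, x$sio2_hydration, x$sio2_roughness))
  cat(sprintf("  area per molecule %.1f A^2 -> head %.2f A, tail leaflet %.2f A\n",
              x$area_per_molecule, th["headgroup"], th["tailgroup"]))
  cat(sprintf("  hydration: head (bound) %.2f, defect %.2f; roughness %.1f A\n",
              x$headgroup_hydration, x$defect_hydration,
              x$bilayer_roughness))
  cat(sprintf("  contrast SLD %.3g /A^2\n", x$contrast_sld))
  invisible(x)
}
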