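# Shared fixtures: the standard synthetic flux profile and the two-angle
# benchmark run schedule (0.7 deg for 7.5 min, 2.0 deg for 30 min, 70
# points each).
std_flux <- function() synthetic_flux_profile()

std_conds <- function(n_points = 70L) {
  list(measurement_condition(0.7, 450, n_points),
       measurement_condition(2.0, 1800, n_points))
}

# a model whose reflectivity is constant and equal to `value` at every Q:
# zero-contrast structure so the specular term vanishes, constant
# background
constant_model <- function(value) {
  refl_model(refl_structure(2.047e-6, list(), backing_sld = 2.047e-6),
             scale = 1, background = value, resolution_dq_q = 0)
}

# parameter set whose single parameter IS the (constant) reflectivity:
# r(xi) = xi through the background term
constant_r_parameter_set <- function(value, lower = value / 4,
                                     upper = value * 4) {
  parameter_set(
    names = "r_level", values = value, lower = lower, upper = upper,
    build = function(v)
      list(refl_model(refl_structure(2.047e-6, list(),
                                     backing_sld = 2.047e-6),
                      scale = 1, background = unname(v[1]),
                      resolution_dq_q = 0))
  )
}

# bare dataset carrier for Fisher computations: q grid plus incident
# counts, no noise realisation needed
design_dataset <- function(q, incident) {
  structure(list(q = q, counts = rep(NA_real_, length(q)),
                 incident = incident,
                 r = rep(NA_real_, length(q)),
                 dr = rep(NA_real_, length(q)),
                 angle = NA_real_, time = NA_real_, seed = NA_integer_),
            class = "nr_dataset")
}

benchmark_free4 <- function() {
  model_parameter_set(benchmark_model(),
                      free = c("layer1.thickness", "layer1.sld",
                               "layer2.thickness", "layer2.sld"))
}
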