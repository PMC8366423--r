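# neutronfi

Fisher information analysis and counting-statistics experiment
simulation for specular neutron reflectometry.

Reflectometry infers the layer structure of a thin film — thicknesses,
scattering length densities (SLDs), interfacial roughnesses — from the
reflected fraction `r(Q)` at momentum transfer
`Q = 4π sin(θ)/λ`. Every measured point is a neutron count, and counts
are Poisson distributed, so the information an experiment carries about
model parameters can be written down analytically instead of estimated
by hours of posterior sampling. For `M` parameters `ξ` over `N`
reflectivity bins,

```
g = Jᵀ M J,     M = diag(s_i / r_i),     ε_j = sqrt((g⁻¹)_jj)
```

where `J` is the Jacobian of the model reflectances with respect to
`ξ`, `s_i` the expected incident counts of bin `i`, and `ε_j` the
Cramér–Rao uncertainty of parameter `j`. Because `g` is linear in
counting time `τ`, uncertainties follow
`ln ε = ln α − ½ ln τ` exactly, which lets you project when an
experiment will reach a target precision — and compare candidate
measurements (angles, times, solvent contrasts) before spending beam
time.

The package is aimed at reflectometry practitioners and method
developers. It provides:

* a compiled Abelès matrix forward model with Névot–Croce roughness,
  Gaussian dQ/Q resolution smearing, scale and background
  (`abeles_reflectivity()`, `model_reflectivity()`);
* faithful time-of-flight experiment simulation from an instrument
  flux profile, with geometric Q binning, the angle-squared slit law
  and Poisson counts (`simulate_measurement()`,
  `simulate_experiment()`, `synthetic_flux_profile()`);
* the Fisher information machinery: finite-difference Jacobians, the
  information matrix, uncertainties, confidence ellipses, an exact
  Poisson Kullback–Leibler oracle, a Gaussian likelihood, differential
  evolution fitting and a Metropolis–Hastings cross-check
  (`fisher_analysis()`, `confidence_ellipse()`, `fit_model()`,
  `mh_sampler()`);
* experimental-design analyses: uncertainty-versus-time scans,
  solvent-contrast scans for a supported DMPC-style bilayer
  parameterised by area per molecule, fitting-bias estimation, and an
  Anscombe/Hotelling comparison of datasets (`uncertainty_vs_time()`,
  `contrast_scan()`, `estimate_fit_bias()`, `compare_datasets()`);
* ASCII readers/writers for reflectivity data and flux profiles, YAML
  model configuration, and a command-line entry point
  (`inst/cli/neutronfi`).

## Worked example

Simulate the built-in two-layer benchmark sample (thick Si and Cu
layers on quartz) on a synthetic white-beam instrument at two angles,
then ask how well four structural parameters are determined:

```r
library(neutronfi)

flux  <- synthetic_flux_profile()
conds <- list(measurement_condition(0.7, 450, 70),    # 0.7 deg, 7.5 min
              measurement_condition(2.0, 1800, 70))   # 2.0 deg, 30 min
model <- benchmark_model()
ds    <- simulate_experiment(model, flux, conds, seed = 42)

ps <- model_parameter_set(model,
                          free = c("layer1.thickness", "layer1.sld",
                                   "layer2.thickness", "layer2.sld"))
fa <- fisher_analysis(ps, ds)
summary(fa)
```

```
Fisher information analysis over 140 bins
                     value  uncertainty  fisher_info
layer1.thickness 7.907e+02 4.443586e-03 7.282906e+04
layer1.sld       1.795e-06 1.041295e-10 1.879807e+20
layer2.thickness 2.979e+02 1.206371e-03 6.992476e+05
layer2.sld       6.385e-06 3.454840e-11 1.325455e+21
condition number of g: 6.04
```

Reading this: a 37.5-minute measurement pins the 297.9 Å Cu-layer
thickness to ±0.0012 Å and its SLD to ±3.5×10⁻¹¹ Å⁻² (one-sigma
Cramér–Rao bounds, given the model and counting statistics — an actual
estimator can do no better). The `fisher_info` column is the FI
diagonal in nats per (parameter unit)²; the condition number is for the
unit-scaled information matrix. Projecting over counting time:

```r
scan <- uncertainty_vs_time(ps, flux, conds, time_factors = c(1, 10, 100, 1000))
scan
```

```
<time scan> 4 factors in [1, 1000]
                 slope  intercept
layer1.thickness  -0.5  -5.416294
layer1.sld        -0.5 -22.985386
layer2.thickness  -0.5  -6.720138
layer2.sld        -0.5 -24.088660
```

Every parameter's log-uncertainty falls with log-time at slope exactly
−1/2: doubling the time budget shrinks every uncertainty by √2, and
the intercepts tell you when a target precision will be reached.

For contrast-variation design of a supported lipid bilayer:

```r
bp   <- bilayer_params()
scan <- contrast_scan(bp, flux = flux,
                      conds = list(measurement_condition(0.7, 900, 40),
                                   measurement_condition(2.0, 3600, 40)),
                      prior_contrasts = contrast_sld_from_d2o_fraction(1))
plot(scan)
```

The scan shows, per parameter, how much information a second solvent
contrast would add after a D₂O measurement — with a characteristic
collapse of the SiO₂-hydration information where the solvent matches
the oxide's SLD (contrast matching makes the layer invisible).

See the vignette
(`vignettes/fisher-information-reflectometry.Rmd`) for the model
conventions, the synthetic flux profile, numerical choices and
limitations.

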