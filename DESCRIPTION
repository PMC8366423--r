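Package: neutronfi
Title: Fisher Information Analysis and Experiment Simulation for Neutron
    Reflectometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling of specular neutron reflectivity from
    stratified layer models (Abeles matrix formalism with Nevot-Croce
    roughness, instrument resolution smearing, scale and background),
    counting-statistics-faithful simulation of time-of-flight
    reflectometry experiments from instrument flux profiles, and
    analytic Fisher information for model parameters under Poisson
    count statistics. Provides parameter uncertainties and confidence
    ellipses from the inverse Fisher information, projection of
    uncertainties over counting time, solvent contrast-variation scans
    for supported lipid bilayer design, fitting by bound-constrained
    differential evolution, and dataset comparison via the
    Anscombe-transformed Hotelling T-squared test.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
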