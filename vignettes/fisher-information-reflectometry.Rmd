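---
title: "Fisher information analysis of neutron reflectometry experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fisher information analysis of neutron reflectometry experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutronfi)
```

## The problem

A specular neutron reflectometry measurement records the fraction of
neutrons reflected from a layered sample as a function of momentum
transfer $Q = 4\pi\sin\theta/\lambda$. Each reflectivity point is a
neutron count, and counts obey Poisson statistics: the uncertainty of a
point with $N$ counts is $\sqrt{N}$. Because the noise model is known
exactly, the information that an experiment carries about the parameters
of a layer model — thicknesses, scattering length densities (SLDs),
interfacial roughnesses, hydrations — can be computed *analytically*,
without sampling a posterior. That is what this package does: it couples
a standard optical-matrix forward model to the Fisher information (FI) of
the Poisson count likelihood, giving sub-second parameter uncertainties,
projections of those uncertainties over counting time, and
information-based comparisons of candidate experimental designs such as
solvent contrast choices for a supported lipid bilayer.

## The model

### Forward model

A sample is a stack of layers between two semi-infinite media. The
unsmeared reflectance $r(Q)$ is computed by the Abelès
characteristic-matrix recursion: in medium $n$ the normal wavevector is
$k_n = \sqrt{(Q/2)^2 - 4\pi(\rho_n - \rho_0)}$, adjacent media are
coupled by Fresnel coefficients damped by the Névot–Croce factor
$\exp(-2 k_n k_{n+1}\sigma^2)$ for a Gaussian interface of width
$\sigma$, and the $2\times2$ interface/phase matrices are multiplied
from the incident medium to the substrate. The kernel is compiled
(`src/abeles.cpp`); an independent pure-R Parratt recursion in the test
suite serves as its oracle. Real SLDs only — absorption, magnetism and
off-specular scattering are out of scope.

The measured curve adds three instrument terms,
$$r_\text{model}(Q) = \text{scale}\times
\langle r \rangle_{\Delta Q} + \text{background},$$
where $\langle\cdot\rangle_{\Delta Q}$ is a Gaussian $dQ/Q$ resolution
average. Conventions worth stating because the field is loose about
them:

* the quoted percentage resolution is the **FWHM** of the Gaussian
  kernel (converted internally by $1/2\sqrt{2\ln 2}$), matching common
  reflectometry practice;
* the background is **not** multiplied by the scale factor — it is
  detector noise, independent of illumination normalisation;
* a layer's `roughness` belongs to its **top** interface (towards the
  beam); `backing_roughness` covers the final interface to the
  substrate.

The resolution average is evaluated by fixed-node quadrature: equally
spaced nodes across $\pm3.5\sigma$ with normalised Gaussian weights. The
default of 101 nodes was chosen by measuring convergence against a
2001-node dense convolution on a fringed two-layer curve (maximum
relative deviation $9\times10^{-5}$); 51 nodes were not sufficient at
the $10^{-4}$ level. Zero resolution short-circuits to the unsmeared
values bit for bit.

### Experiment simulation

`simulate_measurement()` turns a model plus an instrument flux profile
into a synthetic dataset with exactly the noise structure of a
time-of-flight measurement. Wavelengths map to $Q$ at the measurement
angle; each wavelength's flux is assigned wholly to the geometric $Q$
bin containing it (matching the histogramming of time-of-flight events);
bin centres are geometric means of the edges (arithmetic available).
Incident intensity scales as the *square* of the angle relative to the
flux profile's reference angle, because both collimation slits open
linearly with angle. The expected incident count of bin $i$ is
$s_i = \mu_i \tau (\theta/\theta_\text{ref})^2$ and the recorded count
is drawn as $N_i \sim \text{Poisson}(s_i\, r_i)$, giving
$r = N_i/s_i$, $\delta r = \sqrt{N_i}/s_i$. One experiment seed spawns
an independent sub-stream per dataset, so repeated contrasts get
independent noise while the whole experiment stays reproducible.

The bundled `synthetic_flux_profile()` is a deterministic stand-in for a
measured instrument spectrum: a Maxwellian peak
($\lambda^{-5} e^{-2.5(\lambda_p/\lambda)^2}$, peak 2.5 Å) plus a
$1/\lambda$ epithermal tail carrying 10% of the integral — the textbook
two-component moderator description. The tail matters: a pure
Maxwellian spans some twenty decades across a 0.5–12 Å band and would
starve the $Q$-extreme bins of any counts. The default integrated flux
of $10^8$ n s$^{-1}$ at a 0.3° reference angle is a realistic
white-beam level and keeps every bin of the standard two-angle schedule
(0.7° for 7.5 min, 2.0° for 30 min, 70 points each) populated, so the
Gaussian likelihood below is well defined at every point. These are
fixed study conditions, not tuning knobs. What the generator does *not*
emulate: detector efficiency variation, gravity droop, footprint
overfill beyond the $\theta^2$ slit law, and instrument backgrounds
with structure — so passing tests say nothing about those effects in
real data, and absolute count levels of any particular beamline are not
reproduced.

### Fisher information

For $M$ parameters $\xi$ and $N$ bins the information matrix is
$$ g = J^\mathsf{T} M J, \qquad
M = \mathrm{diag}(s_i / r_i), $$
with $J_{ij} = \partial r_i/\partial \xi_j$ estimated by central
differences at $\pm0.5\%$ of each parameter value (absolute fallback of
0.5% of the bound width for a parameter sitting at zero). The model
reflectances $r_i$ here include scale and background — a positive
background is required, since $M$ divides by $r_i$. Multiple datasets
(angles, contrasts) concatenate their bins; shared parameters appear
once, which is how joint multi-contrast information is computed.
Everything uses *model* reflectances, never a particular noise
realisation, so $g$ is a property of the design: it is exactly linear
in counting time, which is why uncertainties obey
$\ln\varepsilon = \ln\alpha - \tfrac12\ln\tau$ with slope exactly
$-1/2$ (`uncertainty_vs_time()` verifies its own regression to
$10^{-6}$).

Uncertainties are $\varepsilon_j = \sqrt{(g^{-1})_{jj}}$, the Cramér–Rao
bound for an unbiased estimator. Inversion is by eigendecomposition
with a scale-invariant condition check: parameters carry wildly
different units (an SLD is $\sim10^{-6}$, a thickness $\sim10^2$), so
conditioning is judged on $D^{-1/2} g D^{-1/2}$ with $D =
\mathrm{diag}(g)$, and a scaled condition number above $10^{10}$ raises
an error naming the degenerate parameter combination (the smallest
eigenvalue's eigenvector). The quadratic form
$\tfrac12\,\Delta\xi^\mathsf{T} g\,\Delta\xi$ is the second-order
expansion of the Kullback–Leibler divergence between the Poisson count
distributions at $\xi$ and $\xi+\Delta\xi$;
`kl_divergence_counts()` computes that divergence exactly and is the
package's own oracle for $g$ (agreement to better than 1% at steps of
$0.1\varepsilon$). We follow the expansion itself and do not enforce
the loose one-nat-per-sigma rule of thumb, which is exact only for a
Gaussian with constant covariance.

Confidence ellipses for a parameter pair use the **marginal** $2\times2$
block of $g^{-1}$, not the conditional block of $g$, because the
ellipses are meant to be overlaid on the 2-D marginals of a sampling
corner plot; the conditional variant is available behind
`marginal = FALSE`.

### Fitting and the sampling cross-check

`fit_model()` minimises the Gaussian negative log-likelihood
$$ -\ln L = \tfrac12\sum_i\left[
\left(\frac{r_i - r_{\text{model},i}}{\delta r_i}\right)^2
 + \ln\!\left(2\pi\,\delta r_i^2\right)\right] $$
by bound-constrained rand/1/bin differential evolution (population
$\max(20, 10M)$, mutation weight 0.8, crossover 0.9, reflection at the
bounds, seed-reproducible), polished with L-BFGS-B using per-parameter
scaling. Differential evolution is implemented in the package itself —
it is a short, fully specified algorithm and keeping it internal makes
the optimizer contract (bounds, determinism) easy to guarantee.
`mh_sampler()` is a deliberately simple random-walk Metropolis–Hastings
chain with uniform priors on the bounds; it exists as a cross-check that
FI uncertainties match posterior widths on well-conditioned fixtures,
not as a production sampler. Proposal tuning (fraction of the bound
width, or absolute scales) affects only mixing, never the stationary
distribution.

### Dataset comparison

`compare_datasets()` asks whether two measurements of the same sample
differ beyond counting noise. Counts are variance-stabilised with the
Anscombe transform $2\sqrt{N + 3/8}$ and differenced bin by bin. The
multivariate observation structure is a genuine design choice (nothing
in the underlying statistics forces one): here each $Q$-bin index
contributes one paired observation with one component per angle
dataset, and a one-sample Hotelling $t^2 = n\,\bar d^\mathsf{T}
S^{-1}\bar d$ with $F$ reference distribution
($F_{p,\,n-p}$ after the usual $(n-p)/(p(n-1))$ factor) tests the mean
difference against zero. A single stitched dataset degenerates to a
paired $t$-test. The statistic is most sensitive to coherent
(same-sign) differences such as scale or background errors; a
pure fringe shift can partially cancel in the per-angle mean.

### The supported bilayer model

The soft-matter application is a DMPC-style bilayer on silicon:
Si | hydrated native SiO₂ | inner headgroups | tailgroups | outer
headgroups | bulk water. Rather than fitting volume fractions, the
model is parameterised by the **area per molecule** $A$: with fixed
molecular volumes, leaflet thicknesses follow as $t = V/A$, so surface
area and thickness trade off exactly inversely. Water enters lipid
layers through surface defects (both head and tail layers) and as bound
water on the hydrophilic headgroups; only the summed water volume
fraction matters for a layer's SLD, which is the volume-weighted
mixture of the dry component SLD $b/V$ and the solvent SLD. The solvent
(contrast) SLD appears as the backing *and* inside every hydrated
layer, which is what makes contrast variation informative — and what
makes a component invisible when the solvent matches its SLD.

Component values are fixed at conventional literature numbers for DMPC
($V_h = 320.9$ Å³, $b_h = 6.01\times10^{-4}$ Å from C₁₀H₁₈NO₈P;
$V_t = 780.1$ Å³, $b_t = -2.91\times10^{-4}$ Å from the two myristoyl
chains; SiO₂ SLD $3.47\times10^{-6}$ Å⁻²) and are deliberately not
fittable: the constant-volume assumption is what ties thickness to area
per molecule. They are inputs of the parameterisation — editable in the
configuration file — not fitted ground truth. The two tail leaflets are
merged into one layer by default (`split_tails = TRUE` separates them).
Water contrast interpolates linearly between pure H₂O
($-0.56\times10^{-6}$ Å⁻²) and pure D₂O ($6.35\times10^{-6}$ Å⁻²).

`contrast_scan()` walks a grid of candidate solvent contrasts (default
100 points across that physical range), builds the joint model set of
already-measured contrasts plus the candidate with all bilayer
parameters shared, and records the FI diagonal per parameter. Because
information over independent datasets adds, a previously measured
contrast can never reduce the joint diagonal — the scan with a D₂O
prior is everywhere at least the single-contrast scan. The SiO₂
hydration information dips to a minimum at the grid point nearest the
SiO₂ SLD: at contrast match the oxide is invisible and its hydration
locally uninformative.

## Numerical choices and degenerate inputs

* Finite differences: relative 0.5% central steps; exactly linear
  parameters (the scale factor) are therefore differentiated to
  rounding error.
* Matrix inversion: eigendecomposition, unit-scaled condition threshold
  $10^{10}$, explicit error with the degenerate direction.
* Empty $Q$ bins (no flux mapping into them) are dropped with a
  warning; a dataset with zero flux everywhere is returned empty.
* Zero-count bins would carry $\delta r = 0$ and are rejected by the
  likelihood with a clear message rather than silently reweighted.
* Ties and bounds in the optimizer: trial vectors reflect off the
  bounds and are then clipped; equal-cost trials replace the incumbent
  (drift towards newer solutions).
* The KL oracle requires $r_i > 0$ at both parameter points; a positive
  background guarantees it.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script fixtures use the two-angle
schedule above with 70 bins per angle (140 points), 200 repeats for the
Poisson moment checks, 50 trials for the null-comparison rate, 40
replicate fits for recovery, $10^5$ Metropolis–Hastings steps for the
sampler cross-check, and 100-point contrast grids — sizes at which every
stochastic tolerance has comfortable margin while the whole suite runs
in minutes on one core.

## Known limitations

* Absorbing (complex-SLD), magnetic and off-specular systems are out of
  scope, as are free-form SLD profiles.
* The FI is the information *available* in the counts; when parameters
  are strongly correlated an actual estimator may extract less, and the
  bound is not bias-corrected (any estimator bias only widens true
  uncertainty).
* The Hotelling comparison's per-angle reduction trades power against
  fringe-shift alternatives for robustness and a clean reference
  distribution; see above.
* Absolute count levels of a real beamline require its measured flux
  profile (`read_flux_profile()`); the synthetic profile reproduces
  statistical structure, not absolute rates.

## A worked example

```{r example, eval = FALSE}
flux <- synthetic_flux_profile()
conds <- list(measurement_condition(0.7, 450, 70),
              measurement_condition(2.0, 1800, 70))
model <- benchmark_model()
ds <- simulate_experiment(model, flux, conds, seed = 42)
ps <- model_parameter_set(model,
                          free = c("layer1.thickness", "layer1.sld",
                                   "layer2.thickness", "layer2.sld"))
fa <- fisher_analysis(ps, ds)
summary(fa)
confint(fa)
plot(fa, "layer1.thickness", "layer2.thickness", k = 1:3)

scan <- uncertainty_vs_time(ps, flux, conds)
plot(scan)
```
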