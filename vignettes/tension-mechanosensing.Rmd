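---
title: "Methods: membrane tension, channel activation and their analysis in tensiopipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane tension, channel activation and their analysis in tensiopipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `tensiopipe`, the assumptions and
tunable parameters of each stage, what the synthetic generators do and do
not emulate, and the numerical and design decisions a maintainer would want
on record. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The experimental picture

A force-controlled micropipette (a hollow-tipped AFM cantilever with a 2-um
aperture) indents an adherent cell with a controlled force `F` (nN) and
then aspirates the membrane with stepped pressures `p` (mbar). Channel
activation (a cytosolic calcium rise, mediated by mechanosensitive cation
channels such as Piezo1) is read out by fluorescence imaging; membrane
tension is read out by the fluorescence lifetime of a planarizable
membrane probe, whose long lifetime component grows with tension. The
package implements the downstream quantitative chain for both readouts,
the force-spectroscopy stiffness readout, and a simplified mechanical
simulator of tension confinement.

## Activation statistics

**Model.** A cell's latent activation threshold at force `F` is logistic
(Boltzmann) with location `a0 + beta*F` and width `b`. The stepped
protocol observes the first 25-mbar multiple at or above the threshold
(ceiling snap: the observed critical pressure is the first step that
reaches the latent threshold), censored at 400 mbar. The cumulative
frequency of observed pressures estimates the activation probability.

**Fitting.** `fit_boltzmann()` minimizes squared deviations of
`1/(1+exp(-(p-a)/b))` from the cumulative-frequency points, mirroring the
original recipe; `chi2_sig` and `chi2_lin` are raw residual sums of
squares (not reduced chi-square) of the sigmoid and of a straight line on
the same points, giving `GoM = chi2_lin/chi2_sig + 1` and the composite
error `sigma + a/GoM`. Initialization uses the interpolated 0.5-crossing
and the logistic quartile spacing `b0 = (p75 - p25)/(2 ln 3)`; when the
CDF does not straddle 0.5 (strong treatments at high force), the location
start is obtained by inverting the logistic at the nearest point, and a
Nelder-Mead restart backs up the Gauss-Newton/BFGS path.

**Which points enter the fit.** Two conventions exist. Evaluating the
ECDF only at *observed* distinct pressures (the package default in
`cumulative_frequency()`, and the convention of its counting examples)
is biased at small n: an extreme-tail point enters the fit only when an
extreme draw occurred, which drags `p_C,50` low by several mbar at
n ~ 40. Evaluating on the *full protocol grid* (zeros below the first
observation, ones above the last) — the natural reading of a "cumulative
histogram" for a stepped protocol — is unbiased; `activation_pipeline()`
infers the grid from the data and uses it. The package exposes both.

**Standard errors.** The least-squares covariance of a sigmoid fitted to
ECDF points understates the sampling error of `a` roughly threefold,
because neighboring ECDF values are strongly correlated. `sigma`
reproduces the original (fit-covariance) definition since it feeds the
composite error formula, but recovery claims in the tests use
cell-resampling bootstrap SEs (`boltzmann_se_bootstrap()`,
`activation_pipeline_bootstrap()`), which measure the estimator's actual
variability.

**Total activation pressure.** Each cell's indentation force is converted
to a pressure with `|slope|` of the `p_C,50(F)` line and added to its
critical pressure; the cumulative histogram of the totals is sigmoid-fitted
for the population half-maximum. Taken literally, this algebra makes the
noiseless half-maximum of totals equal the `p_C,50(F)` intercept
(190 mbar for the control parameterization), while the source experiment
reports a lower value (121 mbar) for the same population; the exact
per-cell conversion used there is not recoverable from the text. The
package implements the literal procedure and the tests document the
identity; the total-activation acceptance target draws totals directly
from a logistic centered at the printed value, as its setup prescribes.

**Parameter edge cases.** Two printed treatment lines are not physically
realizable over the full force range: the margaric-acid line
(117 - 5.6 F) is negative at 25 nN, and the cytochalasin-D line
(167 - 6.3 F) has its half-activation point below the first protocol step
at 25 nN. The generators refuse configurations whose latent mean pressure
is non-positive at the largest force; recovery tests for the MargAc set
therefore restrict to forces where the line stays positive, and the CytoD
slope estimator inherits genuinely high variance (~12% across seeds at
the printed per-force n) from the extrapolated top-force point.

## TCSPC reconvolution and lifetime imaging

**Model.** Bin counts are Poisson around
`N_sig * shape(tau_long, tau_short, frac) + bg`, where `shape` is the
measured IRF convolved with a bi-exponential mixture density, normalized
over the window. Poisson maximum likelihood (not weighted least squares)
is used because it remains correct at low counts per bin. The background
is estimated from pre-rise bins and held fixed. The larger component is
the tension-relevant lifetime.

**Numerics.** The discrete convolution of two center-binned mass
histograms lands sums on bin *boundaries*; a symmetric two-tap average
restores bin-center alignment. Without it the long lifetime is biased by
half a bin width's worth of shift (~ +10% at 10^5 photons in our
configuration) — the generator-versus-model comparison in the tests
guards this. Parameters are optimized in `(log tau, logit frac)` space;
standard errors come from the observed information via the delta method.
A fit whose two lifetimes collapse within 5% is refitted as a single
exponential with a warning. Histograms under the photon threshold
(default 1000, the minimum for a statistically valid per-pixel lifetime)
return a masked result rather than an error, because dark pixels are an
expected feature of membrane images.

**Imaging.** `fit_lifetime_image()` first fits the pooled image histogram
to fix the short component, then fits each valid pixel with the short
component fixed — the same two-stage scheme as the original analysis. Per
pixel precision at the photon threshold is checked against a numerically
computed Cramer-Rao bound (within a factor 2).

**Tension conversion.** `calibrate_tension()` is a least-squares line of
condition-mean tensions (tether pulling) on condition-mean lifetimes
(FLIM) across osmotic conditions; its slope is the conversion factor `c`
in (mN/m)/ns (default synthetic truth 1.325). How tether force converts
to tension is upstream of this package; the calibration consumes tension
values as given. For area-integrated changes, "affected" pixels are those
whose lifetime increase exceeds `k_sigma` (default 2 — the original
criterion is unspecified) times the propagated per-pixel noise SD.

**Kymographs.** Line-scan mode emits per-line ROI means and SD bands and
a step-change verdict (post-contact mean more than 2 pre-contact SDs
above the pre-contact mean). The kymograph *generator* emits per-pixel
lifetime estimates as truth plus photon-limited Gaussian noise
(`sd ~ tau/sqrt(N)`, N >= 500 per pixel) rather than a full TCSPC
histogram per pixel; this keeps kymograph tests desk-scale while
image-mode scenes carry real histograms. A green verdict test therefore
establishes the ROI statistics and detection logic, not the per-pixel
fitting (which the image tests cover).

## Calcium wave analysis

**Preprocessing order matters.** The recipe is denoise, then per-pixel
5th-percentile baseline removal (type-1 quantile, so a pixel dark in
exactly 5% of frames gets its dark level), then spatial Gaussian low-pass
(sigma 1 px default), then max-normalization. A generic Gaussian or
median filter replaces the learned denoiser used on real recordings. If
the baseline percentile is taken on raw noisy data, it sits ~1.6 noise-SDs
below the resting mean and the residual offset defeats threshold
detection — the tests pin this order.

**Detection and speed.** Onset is the first frame with at least
`min_area` (default 5) pixels above threshold (default 0.2 of the
normalized range; the original threshold value is unspecified). Per-frame
activation masks are cleaned with a 3x3 majority filter: blur-correlated
noise otherwise forms spurious supra-threshold clusters that corrupt the
front statistic. The front position is the 95th percentile of active-pixel
distances from the stimulation site (robust to speckle; the original
describes only "the wave front"), and the speed is the least-squares slope
of front distance versus time over 50 frames, with saturated frames (front
at the field boundary) dropped under a warning. Responders show a
threefold peak-over-baseline fluorescence increase; membrane rupture is
flagged by sustained red-channel dye entry and such records are excluded
from activation statistics downstream.

**What the generator emulates.** A sharp (optionally soft-edged) circular
front expanding at constant speed over a uniform cell, Gaussian pixel
noise, optional dye entry. It does not emulate cell morphology,
calcium-buffering kinetics, or inter-cell propagation; a green speed test
establishes estimator correctness on this geometry, not robustness to
arbitrary cell shapes.

## Hertz stiffness

Contact is detected by thresholding the linearly detrended baseline
(default threshold 3 baseline-noise SDs, sustained for 3 samples), then
refined jointly with the modulus by minimizing the fit residual over a
window around the threshold crossing — threshold detection alone is
systematically late by threshold/slope, which matters for the gentle
`delta^{3/2}` onset of a spherical tip. The refinement window expands
adaptively while the optimum pins against its lower edge, and the residual
includes a pre-contact segment where the model is identically zero, which
breaks the contact/modulus degeneracy. Both tip geometries are linear in a
transformed indentation variable, so the modulus is a no-intercept
regression slope; `nu = 0.5` (incompressible cell) by default. The default
geometry is a flat punch of radius 1 um, matching a 2-um cylindrical
probe; the spherical Hertz form is provided as well and cross-geometry
misfits are regression-tested as documented systematic biases.

## Coarse-grained tension simulator

**What it is.** A triangulated disc of harmonic springs under isotropic
pre-strain (rest lengths shortened by `pre_strain`), clamped at the rim,
optionally tethered to static anchor points (the collapsed stand-in for
cortex plus cytoskeleton) at a configurable mean spacing and stiffness,
loaded by a pipette ring (vertical displacement constraint on a ring band,
frictionless, no adhesion) and by aspiration pressure (per-vertex upward
forces `p * A_vertex` inside the ring; 1 mbar = 0.1 nN/um^2). Relaxation
is quasi-static backtracking gradient descent on the total energy, so the
energy trace is non-increasing by construction; force-controlled loading
solves for the ring depth by a secant iteration on the measured vertical
reaction.

**What it is not.** It deliberately simplifies a full particle-based cell
model with explicit solvent and fiber networks: no thermal fluctuations,
no lipid detail, no dynamics, no pipette adhesion, and all parameters are
free configuration with documented defaults. Only qualitative and
limit-law behavior is claimed: monotone tension growth with load, radial
symmetry, the small-deflection membrane solution, and the
anchored-versus-free confinement dichotomy. The sub-micrometer confinement
scale emerges for dense, stiff anchors but its numerical value is
configuration-dependent, and the confinement-length sweep uses levels at
which all profiles are confined (the length is undefined otherwise).

**Local tension.** Each edge's virial `t_e * l_e` is shared half-and-half
between its endpoints and the isotropic tension is half the stress trace,
so the vertex tension is `sum(incident t_e l_e) / (4 A_vertex)`. On a
uniform lattice at isotropic strain `s` this equals
`sqrt(3) k s / (1+s)`, which is also the string tension governing
transverse deflections; the same constant must (and does, in the tests)
reproduce the clamped-disc solution `w = p (R^2 - r^2) / (4 T0)` within
10%. A naive denominator of `2 A_vertex` double-counts shared edges and
fails that closed form by a factor of two.

**Mesh scale.** The default patch (3-um radius, 0.15-um edges, ~1500
vertices) is the coarse preset suitable for pure-R quasi-static
relaxation; a 50-nm mesh over a 6-um patch (~45k vertices) is reachable
through the same configuration but is not the default because relaxation
cost scales super-linearly with vertex count. Boundary vertices and any
vertex with an incomplete lattice neighborhood are clamped, which makes
the affine pre-strained state an exact equilibrium of the discrete system.

## Synthetic data: the stated world

Generator defaults are the conditions of the emulated experiments:
pressure steps of 25 mbar to 400 mbar; the control activation line
(intercept 190 mbar, slope -4.7 mbar/nN, width 12 mbar); 22.4 um/s wave
speed at 50-ms frames; threefold responder threshold; 1000 photons per
image pixel and 500 per kymograph pixel; the 1.325 (mN/m)/ns conversion
slope with five osmotic conditions at the published per-condition cell
numbers; approach at 1 um/s for force curves. Where the sources state no
value we chose once: per-cell calibration SDs of 0.15 ns (lifetime) and
0.2 mN/m (tension), giving condition-level standard errors typical of
n ~ 20 and n ~ 8 averages; movie noise quoted as SNR on the response
amplitude; the unprinted intercept of the wide-force-range activation
line set to 300 mbar so the line stays well positive to 50 nN. Generators
are deterministic given (config, seed); all randomness in tests and in
the acceptance script descends from fixed or caller-supplied seeds.

## Known limitations

- The sigmoid-fit `sigma` (and hence the composite error) inherits the
  original definition's optimism on correlated ECDF points; use the
  bootstrap SEs for inference.
- The reconvolution model assumes the IRF histogram is aligned with the
  decay histogram's time axis; sub-bin IRF offsets are not fitted.
- The wave-speed estimator assumes a single expanding front from a known
  origin; it does not segment multiple cells or merge fronts.
- The simulator's anchors are static; cortical remodeling, viscosity and
  active tension regulation are out of scope.
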