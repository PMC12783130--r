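---
title: "Simulating MINFLUX experiments: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating MINFLUX experiments: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

MINFLUX localizes a single fluorophore by placing an excitation beam with
an intensity minimum (a vortex-phase "donut") at a small set of probe
offsets $b_i$ around the molecule and inferring the position from the
relative photon counts $\hat n_i$. Idealized theory gives the per-photon
precision limit, but real instruments add background, aberrations,
scanner dead times, estimator bias and fluorophore photophysics.
`minfluxsim` models that full chain so performance under realistic
conditions can be quantified before (or instead of) an experiment. This
vignette documents the models, the parameters that matter, and the design
decisions behind them.

## The measurement model

With the effective point spread function $f$ (excitation times detection
efficiency), an emitter at $x$, brightness/power scale $I_0$ and a
dimensionless background $bg$, the expected counts at probe $i$ are

$$ I_i = I_0\,\bigl(f(x - b_i) + bg\bigr), \qquad
   p_i = \frac{I_i}{\sum_j I_j}. $$

Any PSF normalization and $I_0$ cancel in $p_i$; we normalize $f$ to its
maximum over the probed region (disk of radius $L$), so that $I_0$ reads
"expected photons per point dwell at PSF max". Realized counts are
Poisson-distributed around $I_i$ (shot noise), with detection losses
applied as binomial thinning of the emitted photons.

Three analytic PSF profiles are available, each parameterized by a length
scale $\sigma$ (default 150 nm, appropriate for a 1.4 NA objective at
640 nm, placing the first donut intensity maximum near
$\sqrt2\,\sigma \approx 212$ nm):

* donut: $f_d(x) = A\,\frac{|x|^2}{4\pi\sigma^4} e^{-|x|^2/2\sigma^2}$,
* quadratic (its small-offset expansion): $f_q(x) = A\,\frac{|x|^2}{4\pi\sigma^4}$,
* Gaussian: $f_g(x) = A\, e^{-|x|^2/2\sigma^2}$.

The quadratic form deviates from the donut by under 5% for
$|x| \le 0.3\sigma$, which covers the probed region of typical patterns.

## The vectorial PSF

`psf_vectorial()` evaluates the vectorial Debye diffraction integral of a
high-NA objective as a discrete sum over a uniformly sampled pupil
(a semi-analytic DFT: two complex matrix products per field component and
z-plane, exact on the requested sample grid). We adopt the aplanatic
$\sqrt{\cos\theta}$ apodization convention. Phase masks are pupil-phase
functions: a vortex ($0 \to 2\pi$ azimuthal ramp), a top-hat ($\pi$ disk
with equal inner/outer pupil energy for the 3D donut) and half-moon
($\pi$ step) masks. Zernike aberrations and a lateral mask shift
(expressed in mm at the pupil-conjugate plane, converted through a
2.5 mm pupil radius) modify the same pupil function.

Default grids are 10 nm pitch over $\pm1.5\,\mu$m; evaluation between
grid nodes uses separable Catmull-Rom cubic interpolation (exact at the
nodes, linear-precision, smooth enough for finite-difference Fisher
information), returning 0 outside the support.

Two physical details deserve explicit mention:

* **Donut null and polarization.** The default input polarization is
  circular with handedness matched to the vortex charge; the on-axis
  focal intensity is then zero to numerical precision. Mismatched
  handedness (or linear input) fills the minimum via the longitudinal
  field component.
* **Half-moon nodal line.** A $\pi$ step across the pupil gives a
  mirror-antisymmetric pupil and, in scalar diffraction, a strict nodal
  plane. In the full vectorial model the depolarization cross-term
  (proportional to $\cos\theta - 1$) is even under the mirror and leaks
  intensity onto the node: about $1.5\times10^{-2}$ of the peak at
  NA 1.4 with the input polarized along the nodal line, falling below
  $10^{-4}$ by NA 0.5. The tests assert both regimes.

Detection is modeled as a flat-phase vectorial PSF at the detection
wavelength (unpolarized average; a Gaussian of matched FWHM is available
as a fast mode), convolved laterally with the pinhole disk (1 Airy unit
$= 1.22\,\lambda_{det}/\mathrm{NA}$). The pinhole stays referenced to the
pattern center because the fast scanner is not descanned; a misaligned
pinhole mainly costs detection efficiency, which the tests verify
(sub-0.5 nm effect on bias). Calibration-bead convolution uses a uniform
solid-sphere kernel (voxel-center inclusion) and is the mechanism by
which bead measurements fill the donut zero and mimic background.
Experimentally calibrated stacks load from 3D TIFF with grid metadata
from arguments or a JSON sidecar; HDF5 input is not supported because no
R HDF5 reader is available to the package, and TIFF covers the
interchange need.

## Fluorophores

A fluorophore combines motion, brightness (expected detected photons per
microsecond at unit normalized intensity), an emitted-photon budget and a
blinking trace:

* **Diffusion** uses per-coordinate normal jumps of variance $2 D\,dt$
  (with D in $\mu$m$^2$/s numerically equal to nm$^2$/$\mu$s); positions
  are cumulative jump sums. During pattern execution each point
  measurement sees one frozen position, sampled at the point start; live
  Brownian motion is advanced by the exact increment between
  measurements, so no time-step convergence issue arises.
* **Stepping** (motor-like) motion draws exponential waiting times
  (mean $t_{step}$) with fixed step size.
* **Vibrations** are moving fluorophores on sinusoidal trajectories.
* **Bleaching**: the photon budget is initialized from an exponential
  distribution and debited by *emitted* photons, before the pinhole and
  detection losses; the Poisson draw is truncated at the remaining budget
  (an approximation only relevant in the final measurement before
  depletion).
* **Blinking**: alternating exponential on/off dwells. After a
  configurable number of returns from the dark state the fluorophore
  stays off: PAINT-like probes get infinite reactivations, dSTORM-like
  buffers an average of two (geometric), PALM-like proteins none. The
  photon-budget presets (1e4 / 1e5 / 3e5) encode the order-of-magnitude
  hierarchy fluorescent protein < organic dye < cumulative PAINT
  binding, and are deliberately generic rather than dye-specific.

The expected emitted photons in a dwell window are
brightness $\times$ intensity $\times$ dwell $\times$ on-fraction, with
the on-fraction computed as the exact overlap of the on-intervals with
the window.

## Estimators

All estimators are closed-form or few-iteration procedures of the kind
deployable on an FPGA for real-time feedback:

* linearized least squares for donut
  ($x = \frac{1}{L_\sigma^2 - 1}\sum \hat p_i b_i$ with
  $L_\sigma^2 = L^2/8\sigma^2$), quadratic ($x = -\sum \hat p_i b_i$) and
  Gaussian models (with/without center probe);
* an iterative least-squares estimator that re-linearizes $p(x)$ around
  the current iterate,
  $x \leftarrow x + (J^\top J)^{-1} J^\top(\hat p - p(x))$. Its first
  iteration from the origin reproduces the linearized estimator exactly,
  and it extends the low-bias field of view to roughly the pattern size.
  The Jacobian of $p_i(x) = f_i / \sum_j f_j$ has the closed form
  $(\nabla f_i \sum_j f_j - f_i \sum_j \nabla f_j)/(\sum_j f_j)^2$ for
  any probe set, so one analytic expression covers all orbit sizes with
  and without a center point (verified against numeric differentiation);
  defaults are 0.1 nm tolerance, 30 iterations, iterates clamped to
  $|x| \le L$ where the model ceases to be meaningful;
* the 1D maximum-likelihood estimator for the quadratic model at
  $\pm L/2$, returning the bounded root
  $\frac{L}{2}\frac{\sqrt{n_1}-\sqrt{n_2}}{\sqrt{n_1}+\sqrt{n_2}}$ and
  using a center count, when available, to select between the two
  stationary solutions by multinomial likelihood (the likelihood uses the
  background-free quadratic model);
* a direct 1D estimator with the background as a free parameter,
  $x = \frac{L}{4}\,\frac{n_2 - n_1}{2 n_0 - n_1 - n_2}$, which is
  invariant under uniform count offsets and also back-solves brightness
  and background.

Background handling: expected background counts can be subtracted from
the measured counts before estimation (negative results floored at zero,
flagged), or fitted via the direct estimator. Both remove the
center-ward bias that uncorrected background induces.

## Scanners, dead times and sequences

The pattern center is the sum of a slow, descanned scanner position and a
fast, non-descanned scanner position. Recentering moves the pattern
toward the estimate by $2^{-damping}$ (the damping semantics of the
commercial controller are unpublished; the exponential step-down is
isolated in one function). The slow scanner absorbs the accumulated fast
offset when the latter exceeds its configured range (default 200 nm),
costing a slow dead time. Default dead times are 11 us per fast move,
15 us per estimator evaluation and 40 us per slow move, the values
measured on current commercial firmware; time accounting is exactly
additive and tested as such.

Sequence files use a JSON dialect mirroring commercial MINFLUX sequence
files (iterations with `pattern`, `L`, `patDwellTime`, `patRepeat`,
`pwrFactor`, `phtLimit`, `ccrLimit`, `maxOffTime`, `wavelength`; globals
`bgcThreshold`, `ctrDwellFactor`, `damping`, `headstart`, `loclimit`,
`stickiness`, `fieldGeoFactor`), plus a companion JSON assigning
estimator registry names per iteration. Keys whose on-instrument
semantics are unpublished are given documented interpretations:
`patDwellTime` is the per-point dwell; `patRepeat` subdivides that dwell
into repeated sub-scans within the same pattern scan time (the flicker
mitigation mechanism); `ctrDwellFactor` scales the center-point dwell;
`headstart` exempts the first localizations of a candidate from the CFR
check; `bgcThreshold` is compared against each pattern scan's count rate
(counts/ms); `fieldGeoFactor` scales the scouting field of view.

An imaging run alternates hexagonal-grid scouting with a Gaussian beam
(an approximation of the pinhole-orbit search; bleaching by the donut
outside the detection volume is consequently underestimated) and
per-candidate localization through the iteration ladder. A localization
accumulates whole pattern scans until the photon limit, then passes the
photon-rate and CFR checks (center count over mean orbit count,
failing when above `ccrLimit`); failures decrement the stickiness budget
and abandonment follows at zero, at `loclimit`, or after `maxOffTime` of
darkness. Valid localizations therefore always satisfy
$\hat N \ge$ `phtLimit` and cfr $\le$ `ccrLimit`.

## Performance metrics

The numerical Cramer-Rao bound follows the Fisher-information recipe:
central finite differences of $p_i$ at $x \pm \varepsilon/2$ per axis
(default $\varepsilon = 0.5$ nm; halving it moves the result by well
under 0.1%), $F_{ab} = N \sum_i \partial_a p_i\, \partial_b p_i / p_i$,
and $\sigma_a = \sqrt{(F^{-1})_{aa}}$. Because the probabilities come
from the simulated model, the bound automatically includes background,
aberrations, bead effects and nearby emitters. Error summaries use
population ($1/Q$) normalization with
$\mathrm{RMSE}^2 = \mathrm{STD}^2 + \mathrm{bias}^2$ as an exact
identity; RMSE carries the square root so the name is accurate. The
flicker decomposition inverts
$\mathrm{STD}(r, N)^2 = \sigma_{fl}(r)^2 + \sigma_{CRB}(N)^2$, clipping
at zero. MSD fits use lags 2-5 by default because lag 1 is dominated by
localization noise in measured tracks.

## Tracking and the maximal trackable diffusion coefficient

The tracking protocol starts a diffusing emitter under the pattern and
lets the feedback loop follow it; a track counts as successful at 90
consecutive valid localizations, and $D_{max}$ is the diffusion
coefficient at which half the tracks succeed (linear interpolation of
the success-versus-$D$ curve). Loss occurs when a diffusive excursion
outruns the pattern's capture range within one localization time, so
$D_{max}$ is governed by the localization cadence (dwell, photon limit,
dead times) and the pattern size.

The default emitter brightness for tracking studies is 2 photons/us at
the PSF maximum, chosen so the standard sequence (photon limit 500,
0.3 ms per-point dwell) completes a localization in one or two pattern
scans -- the sub-millisecond-to-millisecond cadence of experimental
tracking. The packaged "optimized" tracking sequence is the outcome of a
coarse in-package optimization of the final iteration over pattern size
(75/100/150 nm), photon limit (150/300/500) and per-point dwell
(0.1/0.2 ms) at 12 tracks per point on a geometric $D$ grid: the winner
(L = 150 nm, photon limit 500, dwell 0.1 ms) trades per-localization
precision for capture range and cadence and raises $D_{max}$ by roughly
a factor of three over the standard sequence under these conditions.
Disabling dead times raises $D_{max}$ further, confirming dead times as
a principal limitation.

## What the synthetic scenes do and do not capture

The nuclear-pore fixture (8-fold rings of 50 nm radius with Bernoulli
labeling), diffusing emitters and stepping tracks exercise the
acquisition logic, photophysics and feedback loop with exactly known
ground truth. They do not emulate autofluorescence structure, refractive
index heterogeneity, drift beyond sinusoidal vibration, spectral
crosstalk or dipole-orientation effects; passing tests therefore
validate the measurement chain and estimator statistics, not the full
complexity of a biological sample.

Numerical conventions collected in one place: lengths nm, times us
(sequence-file dwell and dead times in ms, converted on parse); Poisson
photon statistics everywhere; probabilities floored at $10^{-12}$ inside
Fisher information to avoid 0/0 at exact PSF zeros; degenerate
localizations ($\hat N = 0$) are flagged and excluded from estimator
statistics; all stochastic entry points take explicit seeds and restore
the caller's RNG state.

Test problem sizes are chosen to keep the whole suite fast while leaving
Monte-Carlo error well below the asserted tolerances: error-statistics
checks use 2,000-10,000 localizations, tracking checks 8-20 tracks per
diffusion coefficient; the corresponding study-level scripts simply raise
those counts.
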