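# minfluxsim

Realistic in-silico MINFLUX microscopy: simulate the full measurement
chain of a patterned-excitation localization microscope — point spread
function, fluorophore photophysics, scanner feedback loop, on-board
position estimators and acquisition logic — to quantify localization
precision, bias and tracking limits under realistic, imperfect
conditions.

## Who this is for

MINFLUX localizes a single fluorophore by probing it with an excitation
beam featuring an intensity minimum (a vortex-phase "donut") at a set of
offsets $b_i$ on an orbit of diameter $L$, and inferring the position
from the relative photon counts $\hat n_i$. Idealized theory (the
Cramér–Rao bound) predicts remarkable precision per photon, but real
experiments are degraded by background, aberrations and misalignment,
fluorophore blinking and bleaching, estimator bias, and scanner dead
times. `minfluxsim` is for microscopists and method developers who want
to understand, predict or optimize that gap: prototype estimators and
probe patterns, tune acquisition-sequence parameters before going to the
instrument, or judge whether a planned experiment is feasible at all.

## The model in brief

Expected counts at probe $i$ follow
$I_i = I_0\,(f(x-b_i) + bg)$ with probabilities $p_i = I_i/\sum_j I_j$,
where $f$ is the effective PSF (analytic donut/quadratic/Gaussian forms,
or a vectorial Debye-integral model with phase masks, Zernike
aberrations, pinhole detection and bead convolution). Detected counts
are Poisson; fluorophores carry exponential photon budgets and
exponential on/off blinking with reactivation limits. Estimators include
the linearized least-squares family (donut:
$x = \frac{1}{L_\sigma^2-1}\sum\hat p_i b_i$, $L_\sigma^2 = L^2/8\sigma^2$),
an iterative re-linearized LSQ, a 1D maximum-likelihood estimator and a
direct estimator with background as a free fit parameter. Performance is
quantified by a numerical CRB from Fisher information, the
RMSE/STD/bias decomposition, the flicker variance decomposition
$\mathrm{STD}^2 = \sigma_{fl}^2 + \sigma_{CRB}^2$, and MSD-based
diffusion estimation. Abberior-style JSON sequence files drive full
imaging (hexagonal-grid scouting, iterative zoom-in, CFR and photon
quality checks, stickiness) and tracking experiments with measured
hardware dead times (0.011 / 0.015 / 0.04 ms).

See `vignettes/minflux-simulation-methods.Rmd` for the complete account
of the models, parameter semantics and design choices.

## Worked example

Localization precision of an ideal 2D donut at the pattern center:

```r
library(minfluxsim)

psf <- psf_donut2d(sigma = 150)                       # 640 nm / NA 1.4 donut
pat <- define_pattern("orbit", L = 75, K_o = 4,       # 4-point orbit + center
                      dwell = 100, center_probed = TRUE)

compute_crb(pat, psf, N = 500)                        # CRB at 500 photons
#>     x     y
#> 1.224 1.224

sim <- simulate_localizations(pat, psf, n_loc = 5000,
                              photons_per_loc = 500, seed = 2)
compute_errors(sim$est[, 1:2], matrix(0, 1, 2))
#> <performance_summary> Q=5000
#>        [,1]  [,2]
#> rmse  1.237 1.245
#> std   1.237 1.245
#> bias -0.019 0.033
```

The Monte-Carlo spread (1.24 nm per axis) sits within 2% of the
1.22 nm Cramér–Rao bound: at the pattern center the simple linearized
estimator is essentially efficient, and 500 photons buy ~1 nm precision
with a 75 nm orbit.

Tracking a diffusing emitter with the packaged 2D tracking sequence:

```r
cfg <- parse_sequence(system.file("extdata", "tracking_2d.json",
                                  package = "minfluxsim"))
res <- run_tracking(cfg, D = 0.1, n_tracks = 20, seed = 3)
res$success_rate   # 0.9  (fraction with >= 90 consecutive localizations)
res$cadence_hz     # ~716 valid localizations per second
```

At D = 0.1 µm²/s, 90% of tracks sustain the 90-consecutive-localization
criterion at a ~0.7 kHz cadence; sweeping D with `estimate_dmax()` finds
the diffusion coefficient at which half the tracks survive.

A thin command-line wrapper for imaging/tracking/D_max/CRB runs is in
`inst/scripts/minflux-cli.R`.

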