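---
title: "Weight-dependent BCM plasticity with feed-forward inhibition: models and methods"
author: "wdbcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weight-dependent BCM plasticity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wdbcm)
```

# The model

A single rate neuron receives `N` inputs `x` (non-negative firing rates)
through plastic excitatory weights `v`, in parallel with a fixed
feed-forward inhibitory pathway of uniform strength `u` that pools the same
inputs.  The net drive is `h = sum_i (v_i - u) x_i`, so everything can be
written in the *effective* weights `w = v - u`, bounded below by `-u`.  The
activity is `y = g(h)` with `g` linear, rectified, or the saturating
bi-sigmoid used for receptive-field development (`transferSpec()`).

Learning follows the BCM rule.  Per presented pattern,

* weights: `tau_w dw_i/dt = x_i F(y)`, with drive `F(y) = y (y - theta)`;
* sliding threshold: `tau_theta dtheta/dt = -theta + y^2`.

The threshold low-passes the squared activity, so sustained high activity
raises the bar for potentiation; this is what stabilises plain Hebbian
growth without hard weight bounds.

The **weight-dependent** (soft-bound) variant changes only the depression
branch: when `F(y) < 0`, the update becomes
`tau_w dw_i/dt = (w_i + u) x_i F(y)`, i.e. the excitatory weight `v_i =
w_i + u` decays *multiplicatively*.  Relative depression is then
weight-independent while relative potentiation is weaker for strong
synapses, matching the experimental phenomenology of soft-bound
plasticity.  Potentiation is identical under both rules, and the threshold
dynamics are unchanged.  Because depression is proportional to `v_i`,
excitatory weights cannot cross zero: the lower bound enforces itself.

The central scientific point the package exposes: the inhibition strength
`u` acts as a *competition dial*.  Above a critical level `u*` the learning
outcome is the classical winner-take-all BCM fixed point; below it the
stable state responds to several patterns, with a selectivity set by `u`;
for feed-forward excitation (`u < u** < 0`) the weights pin at the bound
`w = (-u, ..., -u)` and the neuron is unselective.

# Stimulus ensembles

`makePair2d(phi)` builds the mirrored unit-norm pair
`x1 = (cos phi, sin phi)`, `x2 = (sin phi, cos phi)`; `phi` tunes how
parallel the two patterns are (`phi = pi/4` is singular and rejected by
all matrix-inverse based analysis).

`makeTriangular(N, K, omega)` and `makeVonMises(N, K)` build circulant
ensembles of `K` shifted copies of one tuning profile over `N` inputs with
periodic boundaries.  The circular distance convention is
`d(i, k) = min(|i - k|, N - |i - k|)` with 0-based indices.  One numerical
caveat worth knowing: for even `N` the `omega = 0.5` triangular profile has
a circulant spectrum (a Fejér-type kernel) with exact zeros, so the
`K x N` pattern matrix is singular.  Simulation and selectivity analysis
are unaffected, but the closed-form winner-take-all weights
`w = K X^{-1} e_m` only exist for well-conditioned widths (e.g.
`omega = 0.7`); the analytic routines check the condition number and
refuse singular ensembles rather than returning noise.

## Image patches

`makeImagePatches()` emulates retinal preprocessing: images are filtered
with a balanced difference-of-Gaussians kernel (`dogKernel()`), circular
patches of exactly `patchPixels` pixels are cut at random positions, and
the ensemble is affinely mapped to `[0, 1]`.  Conventions the package had
to fix where common usage varies:

* "centre width 1, surround 3" is interpreted as Gaussian standard
  deviations in pixels; each Gaussian is normalised to unit sum before
  subtraction, so the kernel sums to zero and annihilates constant
  illumination ("balanced").  The kernel is truncated at four surround
  widths.
* The circular mask takes the `patchPixels` pixel offsets closest to the
  centre, ties broken deterministically in raster order, and flattens them
  in raster order.
* The `[0, 1]` map is a *single* affine map over the whole ensemble, not
  per patch: per-patch normalisation would erase relative contrast between
  patches.  The zero-mean variant subtracts the ensemble grand mean *after*
  that map, so both variants live on the same scale.

`generateSyntheticImages()` provides a built-in greyscale image source with
a `1/f` amplitude spectrum and random Fourier phases, reproducing the
second-order statistics of natural scenes.  It deliberately does *not*
reproduce their higher-order structure (edges, occlusions, sparse
oriented content).  Consequently, training on these synthetic images
exercises the full pipeline and supports directional claims (weight
spread, skewness), but localisation and Gabor-likeness of receptive fields
on real natural images are qualitative questions outside what passing
tests on synthetic images can establish.  Real greyscale images can be
passed in directly (PNG via the optional `png` package).

# Integration scheme

`simulateBCM()` presents the patterns in a randomly permuted, fixed
sequence reused every epoch.  Each presentation lasts one time unit and is
integrated with `1/dt` explicit Euler substeps (default `dt = 0.1`).  Per
substep the threshold is updated first and the weight update uses the same
activity with the freshly updated threshold; with output noise
(`sigmaY > 0`) a single Gaussian deviate is drawn per presentation and
added to the activity throughout that presentation.  The compiled inner
loop (Rcpp) is verified in the test suite against a pure-R loop assembled
from the exported single-step functions, to bit precision.

Why substeps matter: with one Euler step per presentation (`dt = 1`) the
threshold ricochets so coarsely that the two-pattern equilibrium winner
response shifts to `2 - dt/tau_theta` instead of 2 — a 2.5% bias at
`tau_theta = 20`.  The default `dt = 0.1` keeps the discretisation error
well below the intrinsic finite-`tau_theta` effects; the high-precision
two-input analyses in the acceptance script use `dt = 0.005` or finer.
Because the online threshold oscillates within each presentation cycle
even at equilibrium, the package reports the phase-free
`thetaEpochMean()` (time average over the last completed epoch) next to
the instantaneous final value.

Other numerical choices:

* Initial state: effective weights uniform on `(0, 0.1)`, threshold 0.
  Starting the threshold at the mean-field value of the initial responses
  is attractive in two dimensions but lethal for image patches, where
  `mean(y^2) >> typical y` initially drives every pattern into depression
  and silences the neuron permanently.
* Convergence: declared when the *net* weight change over one epoch falls
  below `1e-9 (1 + max|w|)`.  Per-presentation changes cannot be used: at
  the weight-dependent fixed points the individual pattern updates are
  nonzero and only cancel across the epoch.
* Depression guard: a single substep of the multiplicative decay is
  clamped so `v` cannot cross zero (`1 + (dt/tau_w) x_i F < 0` would
  overshoot the bound); occurrences are counted and reported.
* Divergence: `max|w| > 1e6` or non-finite state aborts with the parameter
  regime in the message (typically `tau_theta` too slow relative to
  `tau_w`).
* Time constants: the threshold must average over all `K` patterns yet
  stay fast relative to the weights, `1/K << tau_theta << tau_w`; the
  two-input analyses use `tau_theta = 20`, `tau_w = 200` and the 20-input
  experiments `tau_theta = 200`, `tau_w = 2000` (ten times the pattern
  count, weights ten times slower).  `simulateBCM()` warns outside the
  guidance region.

# Fixed-point machinery

All analysis assumes a linear transfer and the mean-field threshold
`theta(w) = (1/K) sum_k y_k^2`, which makes the learning dynamics an
`N`-dimensional system `meanUpdate(w)`.

* `standardFixedPoints()`: for `K = N` independent patterns the selective
  equilibria are `w = K X^{-1} e_m` with responses `K e_m` and
  `theta = K`; the origin and the equal-response point (`y_k = theta = 1`)
  are appended as the symmetric, unstable candidates.
* `wdFixedPoints2d()`: the fixed points unique to the weight-dependent
  rule need one depressing and one potentiating pattern; stationarity then
  forces a singular 2x2 system whose zero-determinant condition confines
  solutions to a line through `(-u, -u)`.  The search is a bracketed 1-D
  root scan along that line (400-point scan + `uniroot` at tolerance
  1e-14), keeping only roots consistent with the assumed
  depression/potentiation assignment; only the two single-depressor cases
  are enumerated (the all-depress/all-potentiate sectors contain no
  null-clines).  An empty result *is* the answer in the strong-inhibition
  regime.
* `fpStability()`: Jacobians of `meanUpdate` by central differences
  (relative step 1e-6), eigenvalue tolerance 1e-8.  At standard fixed
  points the weight-dependent rule is non-differentiable (the
  depression/potentiation branch is undecided where `F = 0`), so every
  branch assignment of the ambiguous patterns is evaluated and stability
  requires all spectra negative.  The origin's linearisation vanishes
  identically (the drive is quadratic there); such degenerate points are
  resolved by probing the nonlinear field on a small circle — the origin
  comes out unstable, as it must.
* Critical levels: `criticalInhibitionUpper()` (merge point `u*`, one value
  per fixed point, coincident for the mirrored pair) and
  `criticalInhibitionLower()` (pinning level `u**`), with closed forms in
  `phi` (`uStarPair2d()`, `uStarStarPair2d()`) used as cross-checks in the
  tests.  Accessibility of a fixed point (`all(w + u >= 0)`) is always
  *computed* and reported rather than derived from a quoted threshold, so
  asymmetric ensembles are handled correctly.
* `nullclines2d()` / `locateFixedPointsGrid()`: an independent brute-force
  route — sign-change cells of both update components on a weight grid,
  polished by damped Newton iterations — used as the completeness oracle
  for the analytic lists.  The origin is a double zero without sign change
  and is intentionally not counted among the crossings.

## Noise

With zero-mean Gaussian output noise (s.d. `sigma_y`), averaging the rule
gives drive `y(y - theta) + sigma_y^2` and threshold
`theta = (1/K) sum (y_k)^2 + sigma_y^2`.  For the mirrored pair this
yields the closed-form equilibria of `noiseFixedPoints()`: responses
`1 +/- sqrt(1 - sigma_y^2)` with `theta = 2` below the critical noise, and
the collapsed symmetric state `y1 = y2 = 1`, `theta = 1 + sigma_y^2`
beyond it.  Noise weakens competition.

The derivation assumes the threshold is uncorrelated with the activity
fluctuations, which holds only for slow thresholds.  Simulated
time-averaged equilibria at `tau_theta = 20` sit visibly below the
analytic responses; the validation runs therefore use `tau_theta = 200`
(moderate noise) up to `tau_theta = 500` with `tau_w = 5000` near the
collapse at `sigma_y -> 1`, where the susceptibility diverges and
relaxation is slowest.  Equilibrium statistics are time averages of the
noise-free responses over the final portion of the recorded samples
(default: last quarter; the noise validations use the last half), with
batch-means standard errors — a handful of epochs would be far shorter
than the weight autocorrelation time (`~ tau_w`) and would produce
meaningless error bars.

# Metrics and the phase diagram

`selectivity()` implements `s = max_k y_k / sum_l y_l`, ranging from `1/K`
to 1; negative responses (possible transiently with a linear transfer) are
clipped to zero first, and ties are broken by the lowest pattern index.
By this definition the unselective two-pattern state has `s = 1/2`, which
is the value the phase diagram assigns to the pinned regime.
`imbalance()` reports the fraction of peak excitatory drive not cancelled
by inhibition, `m = (max_k E_k - I)/max_k E_k`, evaluated at the preferred
pattern (for circulant ensembles `I` is pattern-independent); `m = 1` iff
`u = 0`, and strongly inhibited, highly selective neurons sit at small
positive `m` — excitation largely cancelled, yet still mean-driven.

`phaseDiagram()` classifies each `(phi, u)` cell analytically: `u > u*`
gives winner-take-all (`s = 1`), `u <= u**` the pinned unselective state
(`s = 1/2`), and in between the selectivity of the weight-dependent fixed
point found by `wdFixedPoints2d()` (a cell whose root search comes back
empty just below `u*` is treated as already merged).  Singular angles are
masked.

# Problem sizes used in the validation suite

The test suite and acceptance script run entirely on synthetic inputs at
desk scale, chosen as the smallest sizes at which the phenomena are
cleanly expressed: two-input analyses to convergence (typically 2e4-4e5
presentations at `dt` between 0.001 and 0.1), noise equilibria over 1e6 to
8e6 presentations, the 20-input triangular experiment over up to 2e6
presentations, and image training with 1500 patches of 400 pixels from six
96-pixel synthetic images over 2e5 presentations.  The compiled loop makes
all of this a matter of seconds.

# Known limitations

* The analytic fixed-point reduction is strictly two-dimensional; in
  higher dimensions more than one pattern can depress simultaneously, the
  determinant condition becomes nonlinear in `w`, and the package follows
  the only practical route: simulation, plus the `K X^{-1}` winner-take-all
  candidates where the ensemble is invertible.
* Stability analysis linearises the mean-field system; it does not address
  the oscillatory/chaotic regimes that arise when `tau_theta` is made fast
  relative to the presentation rate.
* Single postsynaptic neuron only: no lateral interactions, no inhibitory
  plasticity, no spike timing.
* Synthetic 1/f images support directional statements about weight
  distributions, not about the detailed receptive-field structure obtained
  from natural images.
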