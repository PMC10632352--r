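---
title: "ddrquant: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ddrquant: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddrquant)
```

# Scope

`ddrquant` quantifies single-molecule TIRF experiments on activated dynein
transport complexes (dynein--dynactin--activating adaptor, "DDR") and their
regulators Lis1 and Nde1: run frequency and velocity on microtubules,
bait--prey colocalization and comigration, residence-time kinetics, and
mass-photometry population deconvolution. Because raw microscopy of this
kind is rarely deposited, the package pairs every analysis stage with a
synthetic-data generator carrying full ground truth, so each estimator can
be validated by parameter recovery rather than by eye.

# The imaging model

`sim_config()` describes the virtual microscope. Defaults are a 40 × 40 µm
field at 160 nm/pixel (250 × 250 px, the effective EMCCD pixel size after
100× magnification common in objective-type TIRF), 500 frames over a 5 min
acquisition (0.6 s/frame), and an integrated symmetric 2D Gaussian PSF.

* **PSF width** (`psf_sigma_nm`, default 170 nm). Single-molecule emitters
  are diffraction-limited; for visible dyes and a 1.49 NA objective the
  Gaussian approximation to the Airy core has σ ≈ 0.25 λ/NA ≈ 110–180 nm.
  Published analyses of this assay class do not state a width, so 170 nm is
  a documented default, not a fit.
* **Pixelation.** Each emitter contributes
  `N · [Φ(b_x) − Φ(a_x)] · [Φ(b_y) − Φ(a_y)]` photons per pixel (the
  erf-difference "integrated Gaussian"), where `N` is the emitted photon
  count; `render_frame()` is exact up to the ±5σ support window (relative
  truncation < 10⁻⁵).
* **Noise.** Poisson shot noise on signal + background, then EM-register
  excess noise when `em_gain > 1` (a Gamma cascade with mean gain `g`,
  reproducing the classic ≈2× variance inflation), then additive Gaussian
  read noise. Values are clamped at 0.
* **Coordinates.** Continuous nm positions; pixel (1,1) spans
  `[0, 160] × [0, 160]` nm so its center is at (80, 80) nm.
* **Photobleaching** is a single-exponential per-dye process, off by
  default (`bleach_tau_s = Inf`); the assays modeled here are
  oxygen-scavenged and bleaching enters the paper-level analysis only as an
  optional dwell-time correction (below).

# Motility: the stated world

`simulate_motility_movie()` plants processive movers on microtubule
polylines:

* **Landing statistics.** Landings on a filament of length `L` over
  duration `T` are Poisson with mean `f_true · L · T`, uniform in time and
  arc position — the homogeneous landing model implied by counting runs per
  µm per s.
* **Velocity** is drawn once per run from a positive-truncated normal
  (default 500 ± 100 nm/s, the speed scale of reconstituted DDR complexes)
  and held constant; pauses and speed changes within a run are not
  simulated (the detector tolerates them, the truth does not need them).
* **Run length.** The assay's observable is *processive* runs. We define a
  processive run exactly as the detector does — at least
  `min_run_length_nm` (500 nm) of travel *and* at least `min_duration_s`
  (2 s) — plus one frame-interval of travel so that a processive run is
  always resolvable at the sampling rate. Conditional on processivity the
  memoryless exponential law gives length = threshold + Exp(mean); the
  exponential excess mean defaults to 8 µm (multi-micron DDR runs).
  `f_true` is therefore *the rate of processive landings*, which is what
  the run-frequency statistic estimates. Absolute run-length distributions
  are not an output of this package (they are not reported in this assay
  class either).
* **Geometry.** Runs move toward increasing arc length ("minus end" by
  convention), detach at the filament end, and are truncated by the end of
  the acquisition; both truncations are flagged in the truth table.

`simulate_binding_movie()` implements the static colocalization assay: a
fixed bait channel and a prey channel whose episodes alternate exponential
gaps (mean `gap_mean_s`) and exponential dwells (mean `tau_s`, default
21 s — the residence-time scale of dynein regulators). Episodes alive at
the movie end are right-censored in the truth. A warning fires when the
bait density is high enough for PSF overlap (nearest-neighbor spacing
< 4σ).

**What the generator does not emulate:** optical aberrations and drift,
filament bending, dye blinking/photophysics beyond one-step bleaching,
diffusive (non-processive) microtubule binders, and camera fixed-pattern
artifacts. A green recovery test therefore establishes estimator
correctness *under the stated model*, not robustness to every real-world
pathology.

# Localization and tracking

`detect_spots()` is a difference-of-Gaussians bandpass (σ and 1.6σ at the
PSF scale) thresholded at `threshold_k` (default 5) times the robust noise
level `1.4826 · MAD`, followed by 8-neighbor maximum selection and a
minimum-separation rule. `fit_spot()` refines candidates by least squares
against the same integrated-Gaussian model used for rendering
(amplitude, x, y, σ, offset), rejecting edge-clipped windows, σ outside
[0.5, 4] px, and fits indistinguishable from flat background. On noiseless
frames the fit returns the truth to < 10⁻³ px; under shot noise its
precision tracks the σ/√N photon limit within a factor of two (both are
asserted in the acceptance suite).

`link_tracks()` is greedy nearest-neighbor linking, closest pairs first,
one-to-one, with displacement cap `max_disp_nm` (default 640 nm = 4 px,
comfortably above 500 nm/s × 0.6 s) and gap closing up to `max_gap_frames`
(default 2). Greedy distance-sorted assignment is deterministic given the
input order; no motion model is used.

# Kymographs and run detection

`build_kymograph()` samples each frame by bilinear interpolation along the
filament polyline (bin = one pixel) averaged over `width_px` perpendicular
offsets; rows are time increasing downward, columns arc length — the
conventional display. Kymographs are provided for visualization and
cross-checking; the canonical run detector works on tracks.

`detect_runs()` projects tracks onto the filament (association radius
320 nm = 2 px) and extracts maximal unidirectional arc-length excursions,
tolerating pauses up to `max_pause_s` (3 s) and sub-tolerance jitter
(`step_tol_nm`, 80 nm); a reversal beyond tolerance ends the run.
"Processive" is nowhere defined in the source assay literature, so the
thresholds (500 nm, 2 s) are explicit, configurable parameters.

Three measurement corrections make the frequency estimator calibrated
(each is exact under the stated world, none is a tuned constant):

1. **Half-frame correction.** A mover enters before its first sampled
   frame and leaves after its last, so the frame-quantized duration and
   displacement each gain one frame-step; without this, runs near the
   processivity thresholds are systematically rejected.
2. **Censoring exemption.** Excursions truncated by the filament end or
   the end of the acquisition are counted as runs (they are censored, not
   short) once they displace at least `censored_min_disp_nm` (1 px).
   Segments already moving at the movie start are flagged censored but are
   *not* exempt — a landing outside the observation window should not be
   counted on the strength of its tail.
3. **Border corrections.** Landings within `end_exclusion_nm` (default
   1 µm in the pipeline; 0 in the bare function, which keeps the textbook
   `n/(L·T)` arithmetic) of the destination end are dropped and the
   filament length reduced accordingly — the spatial analogue of edge
   correction in spatial statistics. Temporally, a landing is countable
   only if sampled in ≥ 2 frames, which happens exactly when it lands
   before `T − 1.5·Δt`; the pipeline normalizes by that observable window.

With all three, the per-microtubule frequency
(`run_frequency()`: runs / (effective length × observable duration),
summarized as mean ± sd across filaments, each filament one replicate) is
unbiased to ≈0.1% on simulation — well inside the 2-Monte-Carlo-s.e.
acceptance band at 200 replicates.

Filaments shorter than 10 µm are excluded (`filter_microtubules()`,
boundary inclusive: "longer than 10 µm" is read as ≥ 10 µm and
documented). `normalize_frequency()` divides by the reference condition's
mean, so the reference normalizes to exactly 1. `assign_tracks_to_paths()`
resolves filament crossings by assigning each track to the filament
minimizing its median perpendicular distance; without it, movers crossing
another filament are double-counted (+15–20% at realistic filament
densities).

# Colocalization, comigration, release

`match_spots()` performs one-to-one greedy matching, closest pairs first,
within 300 nm (the standard peak-to-peak cutoff for two-color
single-molecule colocalization), reporting matched bait / total bait. On
instances small enough to enumerate, greedy matching attains the exhaustive
optimum (asserted over 10³ random instances). `chance_colocalization()`
gives the random-overlap baseline `1 − exp(−ρπr²)` for prey density ρ; it
is provided for background correction but not applied by default, since
the source analyses do not describe such a correction.

`comigration_fraction()` calls a run comigrating when a single
second-channel track stays within the radius for ≥ 80% of the run's frames
(`min_overlap_fraction`, a documented default). `release_latency()`
measures the delay between prey disappearance (presence by intensity
threshold `background + 3·noise sd` with 2-frame hysteresis, since no
criterion is published) and motility onset; complexes whose prey outlives
onset are "comigrated", baits that never move are censored and reported
separately.

# Dwell-time kinetics

`extract_dwell_events()` turns presence series into episodes. Durations
are quantized to frame intervals; an episode seen in `k` frames is
reported as `k·Δt` — the `(k−1)·Δt` span plus half a frame at each edge.
Events touching the final frame are right-censored.

`fit_exponential()` offers two estimators of the mean residence time τ:

* **Censored MLE** (default): τ̂ = (sum of all durations, censored
  included) / (number of uncensored events), with analytic s.e. τ̂/√n_unc.
  This is the correct treatment of acquisition-end truncation; ignoring
  censoring biases τ̂ downward (a directional test asserts this).
* **Least-squares survival fit**: `exp(−t/τ)` fitted to the empirical
  1-CDF — the convention in the single-molecule literature, provided as a
  compatibility mode; it ignores censoring (with a warning) and takes its
  s.e. from the fit covariance.

The analytic s.e. is canonical where the two differ. An opt-in
photobleaching correction inverts `1/τ_obs = 1/τ_true + 1/τ_bleach` with a
user-supplied bleach time. Coverage of τ̂ ± 1.96 s.e. is calibrated
(93–97% at n = 500 with 20% censoring; asserted).

# Mass photometry

`mp_calibrate()` is an ordinary least-squares contrast→kDa line through
protein standards. `fit_mixture()` decomposes a mass histogram into K
skewed Gaussian populations. The vendor software's skew parameterization
is not public, so the Azzalini skew-normal (location ξ, scale ω, shape α)
is adopted; a population's reported mean mass is the distribution mean
ξ + ωδ√(2/π), δ = α/√(1+α²).

Fitting is EM under the hierarchical representation
`y = ξ + ωδ·|U| + ω√(1−δ²)·V`: the E-step uses exact truncated-normal
moments of the latent `|U|`, the M-step is conditional maximization of
(ξ, then ωδ, then the residual variance), so the observed log-likelihood
is nondecreasing — asserted on every run, every iteration. Ten restarts
from quantile-spread (jittered) initializations guard against local
optima; the scale is floored at 10⁻⁴ of the sample sd to prevent
degenerate spikes; label switching is resolved by sorting components by
location. K is user-supplied (the experimenter knows the candidate
stoichiometries); `population_percentages()` reports weights as integers
summing to exactly 100 by largest remainder, remainder ties going to the
later component.

# Pipeline, statistics, labeling corrections

`run_pipeline()` drives simulate → track → runs → frequency →
normalization per condition (plus optional dwell and mass-photometry
sections) from one YAML config and writes CSV/JSON reports plus a
provenance header (seed, parameters, package version), making every number
reproducible from (config, seed) alone — the acceptance suite asserts
byte-identical re-runs against a committed golden report.

Condition comparisons use Welch's two-sided unequal-variance t test on
per-filament (or per-field) values — no pooling, no multiple-comparison
correction (raw p-values are the convention in this literature, and that
choice is documented rather than silently changed).

Labeling stoichiometry: a homodimer whose monomers are labeled
independently with probability p is visible with probability
`1 − (1−p)² = 2p − p²` (`dimer_labeling_probability()`; 0.65 → 0.88,
0.50 → 0.75), generalized to n-mers by `labeling_probability()`.
`correct_fraction_for_labeling()` divides an observed colocalized fraction
by the complex-level visibility, clipping at 1 with a warning — provided
because incomplete labeling caps observable colocalization well below
100%.

# Numerical choices and degenerate inputs

* Spot fits run BFGS on (x, y, log amplitude, offset, log σ) from a
  centroid start; non-convergence, out-of-bounds σ, or sub-noise amplitude
  return a typed failure instead of a spurious localization.
* The survival curve is by construction a right-continuous step function
  with S(0) = 1; this is asserted on every output.
* `two_sample_test()` refuses degenerate inputs (n < 2 or zero variance in
  both groups) rather than returning NA.
* Exponential-fit inputs with fewer than 20 uncensored events warn; only
  zero uncensored events is an error (the closed form remains exact at any
  n ≥ 1, and the package's own worked examples rely on that).
* All simulators derive every draw from a single configured seed; fixing
  it makes movies, truth tables and reports byte-identical.

# Known limitations

Filament tracing from images is out of scope (paths are supplied as
polylines); localization is 2D symmetric-Gaussian only (no astigmatic 3D,
no filament PSF); linking is motion-model-free greedy assignment and will
fragment at high density; the dwell model is single-exponential (no
multi-state kinetics); free 1D-diffusive microtubule binders can
occasionally satisfy the processivity thresholds — the detector bounds,
but cannot eliminate, such false positives; and the chance-colocalization
correction assumes spatially homogeneous prey.
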