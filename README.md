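# ddrquant

Single-molecule quantification for in vitro reconstitutions of dynein
motility and its regulation. The package implements the analysis chain
behind multi-color TIRF experiments on activated
dynein–dynactin–adaptor ("DDR") complexes and the regulators Lis1 and
Nde1 — and, because raw movies of this kind are rarely deposited, a
ground-truth synthetic-data generator that stands in for the microscope so
every estimator is testable by parameter recovery.

## Who it is for

Single-molecule biophysicists quantifying motor-protein assays:

* **Run frequency** — processive landings per µm of microtubule per second,
  per filament: `f = n_runs / (L · T)`, summarized mean ± sd over
  filaments and normalized to a reference condition.
* **Velocity** — per-run `|Δ arc| / Δt` from the start and end of each
  processive excursion.
* **Colocalization** — fraction of bait spots with a prey peak within
  300 nm (one-to-one, closest first), with the Poisson chance baseline
  `1 − exp(−ρπr²)` available as a correction.
* **Residence times** — dwell (1 − CDF) survival analysis with
  right-censoring; censored MLE `τ̂ = Σ durations / n_uncensored` (s.e.
  `τ̂/√n_unc`) or the literature's least-squares `exp(−t/τ)` survival fit.
* **Mass photometry** — skew-normal (Azzalini) mixture deconvolution of
  mass histograms by monotone EM, reporting each population's mean mass
  and percentage.
* **Labeling corrections** — a homodimer with per-monomer labeling
  probability `p` is visible with probability `2p − p²`
  (0.65 → 0.88, 0.50 → 0.75).

Sub-pixel localization (integrated-Gaussian PSF fits), greedy
nearest-neighbor tracking, kymograph construction, comigration and
release-latency analysis, Welch tests, and an end-to-end YAML-driven
pipeline with byte-reproducible reports round out the chain. The methods
vignette (`vignettes/ddrquant-methods.Rmd`) documents every model,
default and correction.

## Worked example

Simulate a motility experiment at a known landing rate, recover it, and
fit a censored residence-time model:

```r
library(ddrquant)

cfg <- sim_config(frame_interval_s = 0.6, n_frames = 500, rng_seed = 7)
set.seed(7)
paths <- lapply(1:20, function(i)
  mt_path(rbind(c(2000, 1900 * i),
                c(2000 + runif(1, 15000, 30000), 1900 * i)), id = i))

sim    <- simulate_motility_movie(cfg, paths, f_true = 2e-3, render = "none")
tracks <- truth_tracks(sim$truth, cfg)
res    <- analyze_motility(tracks, paths, cfg)
res$frequency
#> run frequency: 0.00202 +/- 0.000485 runs um^-1 s^-1 (mean +/- sd, n = 20 MTs)
```

The configured truth was `f_true = 2e-3` runs µm⁻¹ s⁻¹; the per-filament
mean recovers it within its sampling error, and the uncensored run
velocities average 502 ± 101 nm/s against a configured 500 ± 100.

```r
set.seed(8)
d <- rexp(500, 1 / 21)            # dwells, mean 21 s
C <- 21 * log(5); cen <- d > C; d[cen] <- C   # ~20% right-censored
fit_exponential(data.frame(duration_s = d, censored = cen))
#> residence time: 19.8 +/- 0.977 s (mle, n = 500 events, 88 censored)

round(dimer_labeling_probability(0.65), 2)
#> [1] 0.88
```

An end-to-end run from a config file:

```r
run_pipeline(system.file("extdata", "pipeline_demo.yaml",
                         package = "ddrquant"),
             out_dir = "demo_out")
```

writes `summary.csv`, `frequency.csv`, `runs.csv`, `dwell_fit.json`,
`mixture.json` and a provenance header; rerunning reproduces every file
byte for byte.

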