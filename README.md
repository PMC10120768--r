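# vrplace

An R package for analyzing position-correlated neural activity in
two-photon calcium-imaging sessions recorded while head-fixed mice run on
circular virtual-reality (VR) tracks. It is aimed at systems-neuroscience
labs who have cellular fluorescence traces (e.g. Suite2p output) aligned to
a VR trajectory and want a tested, reproducible path from raw traces to the
standard population-coding statistics — plus a fully seeded synthetic
session generator so every stage can be validated against planted ground
truth without any private data.

## What it computes

Given cell-by-time soma/neuropil fluorescence `F_soma`, `F_neuropil`, a
position trace on a circular track of length `L` (100 bins), velocity,
licks and rewards:

- **Pre-processing** — neuropil correction
  `F = F_soma − 0.7·F_neuropil`, running-minimum baseline
  `F0(t) = min over (t−t2, t]` of the `t1`-smoothed trace
  (`t1 = 1 s`, `t2 = 15 s`), `ΔF/F = (F − F0)/F0`; velocity-gated
  (≥ 1 cm/s), occupancy-normalized laps × bins × cells rate tensor.
- **Place-field criterion** — lap-averaged trace smoothed with a 5-bin
  Hanning window; peaks > 3.5× the trace median are candidates; boundaries
  grow to the first bin below the median or the nearest qualifying trough;
  fields must beat 3.5× baseline (`q50 − q05` of all activity) on
  `max(⌈M/3⌉, 5)` laps and measure 20–150 cm. Cells with ≥ 1 field are
  position-correlated cells (PCCs).
- **Spatial information** (bits/s) `SI = Σᵢ pᵢ fᵢ log₂(fᵢ/f̄)` with a
  100× circular-shift shuffle null, and **sparsity**
  `(Σ pᵢ fᵢ)² / Σ pᵢ fᵢ²`.
- **Bayesian decoding** — Poisson likelihood
  `P(x|n) = C (∏ᵢ fᵢ(x)^{nᵢ}) exp(−τ Σᵢ fᵢ(x))` over non-overlapping
  `τ = 3 s` windows, leave-one-lap-out, circular error, per-lap error
  summaries, best-5-lap error, error-exceedance (> 20 cm) learning curves.
- **Population dynamics** — 100×100 population-vector (PV) correlation
  matrices over 3-lap windows, diagonal means across the familiar→novel
  teleportation; z-scored group activity of familiar-only / both /
  novel-only PCCs; in/out-of-field ratio (30 cm window); lap-wise circular
  field COM shift and field-size expansion.
- **Remapping statistics** — field-location correlation across
  environments (with 5-bin tunnel exclusion), observed vs expected
  (product-law) PCC overlap, and rate-remapping variance: SD of per-lap
  peak activity by zone × configuration epoch, with a speed-at-peak
  control.
- **Object tuning** — activity aligned to a 4-bin window around each of 4
  shifting objects and 6 potential slot positions, against a 1000-draw
  random-alignment null; tuned iff (1) lap-mean − SEM beats the null's
  97.5th percentile at some window bin and (2) window-mean z > 2.3263
  (p = 0.01, one-sided).
- **Behavior** — lick precision = anticipatory lick-bins /
  (total − post-reward lick-bins); chance level 1/9.
- **Synthetic sessions** — `simulate_session()` plants place fields (with
  onset laps, ramps, gain jitter, optional backward COM drift),
  object-locked cells and untuned cells on realistic trajectories
  (tracks 314–503 cm, 7 Hz frames, ~15 cm/s with pauses, teleportation at
  the tunnel midpoint, 4-objects-into-6-slots tables with 360
  arrangements), renders GCaMP6s-like fluorescence, and returns the ground
  truth for parameter-recovery tests.

## Worked example

```r
library(vrplace)
sim <- simulate_session(scenario_config("teleportation", seed = 42,
                                        n_cells = 120))
rec <- sim$rec
pcc_fam <- classify_pcc(bin_activity(rec, rec$envs$familiar, signal_kind = "dff"),
                        si_binned = bin_activity(rec, rec$envs$familiar,
                                                 signal_kind = "deconv"),
                        seed = 1)
pcc_nov <- classify_pcc(bin_activity(rec, rec$envs$novel, signal_kind = "dff"),
                        si_binned = bin_activity(rec, rec$envs$novel,
                                                 signal_kind = "deconv"),
                        seed = 1)
dec <- decode_loocv(rec, rec$envs$familiar)
ov  <- overlap_vs_expected(pcc_fam, pcc_nov)
lp  <- lick_precision(rec, rec$envs$familiar)
```

prints (via the corresponding `sprintf` calls):

```
PCC fraction: familiar 0.200, novel 0.183 (planted 0.242 / 0.183)
familiar decoder error: mean 10.4 cm, best-5-lap 7.2 cm
PCC overlap: observed 0.042 vs expected 0.037
lick precision (familiar): 0.38 (chance 0.111)
session QC: pass
```

The detected PCC fractions track the planted allocation (field detection
is conservative near onset laps), the leave-one-lap-out decoder recovers
position to ~10 cm on a 314 cm track from 120 cells, the observed PCC
overlap sits at the independence product, and measured lick precision
matches the generator's 0.40 target against the 1/9 chance level.

## Pipeline & CLI

`run_pipeline(rec, out_dir, pipeline_config(seed = 1))` executes
QC → preprocessing → tuning → decoding → dynamics → remapping → object
tuning → behavior and writes one tidy CSV per product plus a JSON
manifest. Sessions are stored as a single HDF5 file (or a CSV directory
for toolchain-free inspection) via `write_session()` / `read_session()`.
A command-line front-end lives at
`system.file("cli", "vrplace.R", package = "vrplace")`:

```sh
Rscript vrplace.R simulate --scenario teleportation --seed 1 -o sess.h5
Rscript vrplace.R run --input sess.h5 --out results/ --seed 1
```

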