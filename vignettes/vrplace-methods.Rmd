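---
title: "Models, thresholds and design choices in vrplace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, thresholds and design choices in vrplace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters with their
defaults and units, what the synthetic-data generator does and does not
emulate, the numerical choices made where the method descriptions left
room, and the known limitations. Every empirical statement here is one the
test suite or `scripts/acceptance.R` computes itself.

## The setting and the data model

Head-fixed mice run laps on circular virtual-reality tracks (314–503 cm,
always divided into 100 position bins so cross-environment matrices stay
square; bin size therefore varies 3–5 cm). Every environment shares a
30 cm tunnel whose midpoint defines position 0 and the lap start; an
instantaneous "teleportation" between environments is executed while the
animal is inside the tunnel, so environment switches are constrained to
tunnel bins by the session validator. Two hidden reward sites exist per
environment. In the object task the track (377 cm) is split into two equal
zones; zone B contains six equidistant slot positions of which four hold
visually distinct objects, reshuffled injectively at each lap start in the
shifting/destabilized configurations (6·5·4·3 = 360 arrangements).

A `SessionRecording` holds time-aligned traces (soma and neuropil
fluorescence, optional precomputed ΔF/F, optional deconvolved events),
trajectory, lick/reward events, and one `EnvironmentSpec` per environment.
Two interchangeable on-disk layouts exist (HDF5 file, CSV directory); the
round trip is lossless and tested field by field.

## Pre-processing

`F = F_soma − c·F_neuropil` with `c = 0.7` (range [0, 1]). The baseline
`F0(t)` is the minimum, over the trailing window `(t − t2, t]`
(`t2 = 15 s`), of the trace smoothed by a running mean over `t1 = 1 s`;
`ΔF/F = (F − F0)/F0` with `F0` floored at `1e-6` times the 95th percentile
of `F` (a scale-free guard, so all-zero traces give exactly zero). The
running mean is *centered* by default — only the minimum is defined as
backward-looking, so the mean's laterality is a genuine choice; a trailing
mean is available via `t1_centered = FALSE`. The trailing minimum uses a
sparse-table doubling scheme, exact and O(n log w); the unit tests compare
it to a brute-force per-sample loop.

Binning removes samples slower than 1 cm/s from numerator *and* occupancy
(stationary periods are never analyzed), then divides the accumulated
signal per (lap, bin) by the time spent there. One unit subtlety the tests
pin down: ΔF/F is a level and is time-averaged (`Σ x·dt / Σ dt`), whereas
deconvolved events are counts per frame and become a rate
(`Σ events / Σ dt`, events/s). Incomplete first/last laps of each
environment block are dropped by default (`drop_partial_laps`), a lap
counting as complete when its pre-gated samples reach both ends of the
track; the flag exists because there is no canonical treatment of partial
laps at session boundaries.

Convention: deconvolved events feed spatial information and decoding;
ΔF/F feeds everything else. If events are absent, the positive part of the
ΔF/F first difference substitutes, with a logged message.

## The three-step field criterion

Step 1 finds candidate peaks on the lap-averaged trace smoothed with a
5-bin Hanning window: local maxima above 3.5× the smoothed trace's median.
Boundaries then grow outward along the **raw** lap-average — the smoothing
exists to stabilize peak finding, and growing boundaries on the smoothed
trace would systematically widen every field by the kernel's support,
making the 20 cm minimum unreachable for genuinely narrow fields. Growth
stops at the first bin below the trace median, or at the closest trough
after which the trace falls below 70% of the peak, whichever comes first;
the stopping bin itself (crossing or trough) belongs to no field, and
overlapping candidates are merged keeping the higher peak. Step 2 requires
the per-lap in-field peak to exceed 3.5× baseline (50th − 5th percentile
of the cell's activity over all bins and laps) on at least
`max(⌈reliability_frac·M⌉, 5)` laps. The criterion's usual statement
pairs the lap fraction with the 5-lap floor without fixing the fraction;
`reliability_frac = 1/3` is the default because a "whichever is greater"
rule is only meaningful if the fraction is comparable to 5 laps at typical
session lengths (M ≈ 15), and it is exposed in `tuning_config()` rather
than hidden. Step 3 keeps sizes in [20, 150] cm.

These percentile-anchored thresholds assume a non-degenerate activity
distribution: on a noiseless synthetic trace whose off-field bins are all
exactly equal, the median and the 5th percentile coincide and both the
candidate threshold and the step-2 baseline collapse to zero. The test
fixtures therefore plant a deterministic per-lap baseline "hash"
(sinusoid with lap-varying phase) that mimics the nonzero activity floor
of real ΔF/F; this is a property of the criterion, not of this
implementation.

## Spatial information and sparsity

`SI = Σᵢ pᵢ fᵢ log₂(fᵢ/f̄)` in bits/s, with `pᵢ` occupancy probability,
`fᵢ` the lap-averaged event rate and `f̄ = Σ pᵢ fᵢ`; zero-rate bins
contribute zero, and a silent cell reports SI = 0 with a flag. The rate
(bits/s) form is the default because results are quoted in bps; the
per-event (bits/spike) form would divide by `f̄` and is trivially derived
from the emitted columns. The null circularly shifts each lap's binned
activity by an independent integer in 1..99 and recomputes, 100 times, one
seeded generator per session. Sparsity is `(Σ pᵢ fᵢ)²/Σ pᵢ fᵢ²`: 1 for
uniform activity, 1/N for one active bin among N — both closed forms are
asserted in the tests.

## Bayesian decoding

Tuning curves `fᵢ(x)` are Gaussian-smoothed (circular, σ = 2 bins by default,
exposed in `decoder_config()`) mean rates over all
laps except the decoded one. Retained samples of the decoded lap are cut
into non-overlapping windows of τ = 3 s (windows are assumed
non-overlapping; a sliding variant would only correlate adjacent
estimates). With `nᵢ` the summed events in a window of retained duration
`T` (truncated at lap boundaries; trailing windows shorter than τ/2 are
dropped), the log posterior under a uniform prior is
`Σᵢ nᵢ log fᵢ(x) − T Σᵢ fᵢ(x)`, normalized to sum to 1 — the tests verify
this against a hand-evaluated Poisson likelihood and check normalization
on every window. Rates are floored at `0.01/τ` events/s to keep the
likelihood finite. Decoding error is the *circular* distance
`min(d, L−d)` — bins 1 and 100 are physically adjacent — although the
literal `|Δ|` is available (`circular_error = FALSE`) for strict
replication of the published definition. On 55 planted reliable place
cells tiling 377 cm, median leave-one-lap-out error is under 2 bin widths
(acceptance suite).

## Population dynamics and remapping

Population vectors average cellwise rates over 3-lap windows; matrix
entries are Pearson correlations between PVs at all bin pairs, the
diagonal mean requiring ≥ 50 finite entries (sparse-PV guard). The three
timecourse variants (reference = final 3 familiar laps; novel laps 13–15
vs earlier; each interval vs 7 laps later) use non-overlapping triples —
both a sliding and a non-overlapping reading are defensible, and the
non-overlapping one keeps the series' points independent; sliding windows
are left for visualization.

Circular COM uses the vector-mean angle of in-boundary bins, immune to
the 0/100 seam. Lap inclusion for COM reuses the step-2 in-field activity
rule, starting at the field's onset lap. Two caveats the synthetic
recovery experiments make explicit: (i) COM within a *fixed* boundary is a
truncated estimator — drift of a field whose mass reaches the boundary is
attenuated toward zero, so drift recovery is only unbiased for fields
narrow relative to their boundaries; (ii) the ~1.5 s calcium kernel smears
ΔF/F forward along the track by roughly `v·τ_decay` ≈ 20 cm, so the
acceptance test detects fields on ΔF/F (the channel field detection is
defined on) but measures per-lap COM on the event channel. With 40 narrow planted fields drifting
−1 cm/lap, the pooled regression slope is recovered within 20%.

Rate-remapping variance z-scores each cell over the whole session —
per-epoch z-scoring would erase exactly the between-epoch rate changes
under test — convolves each lap with the 5-bin Hanning window, takes the
per-lap peak (location free), and computes the SD across laps per
configuration epoch; cells are assigned to zone A/B by their across-lap
peak. The speed control repeats the aggregation on the lap's mean running
speed in that lap's peak bin. The epoch boundary assigns the transition
lap to the later epoch, since object reconfiguration takes effect at lap
start.

## Object-versus-position tuning and its false-positive budget

Activity is aligned to a 4-bin window ending one bin after the landmark
(≈ 9 cm before to 3 cm after at 3.77 cm bins). The per-cell null aligns
every lap to an independently drawn slot (uniform over the six permitted
positions — a continuous-position alternative was considered and left out
because objects only ever occupy slots), 1000 draws. Tuning requires both
(1) lap-mean − SEM above the null's per-bin 97.5th percentile at some
window bin (the percentile is computed per window bin, not pooled; SEM
uses n = laps with the n−1 SD), and (2) window-mean z above
`qnorm(0.99) = 2.3263` against the null's window means.

The nominal budget — 1% per slot, ≤ 6% for any of six — assumes the
window-mean statistic is Gaussian under the null. The acceptance suite
measures the actual rate on 500 simulated untuned cells with realistic
sparse activity (~0.2 ev/s) and finds ~8–10%, with the z statistic itself
calibrated (mean 0, SD 1.0 across cells): the lap-averaged window
activity of sparse calcium signals is right-skewed at M = 15 laps, which
lifts the one-sided tail beyond its Gaussian value. Dense continuous noise
(iid exponential rates) satisfies the budget (~1% per slot, ~4.7%
any-of-six). The corresponding acceptance check is deliberately left
failing rather than re-tuned; the double criterion — the one actually
used for classification — has a measured false-positive rate far below
the z-only rate (~0.5–1.5%), and that ordering is asserted green.

## Behavior

Licks are binarized per (lap, bin) so bursts weigh no more than single
exploratory licks. The five bins before each reward bin are anticipatory;
the reward bin plus the four after it are post-reward — the 100 − 10 = 90
scored-bin arithmetic constrains but does not uniquely place the reward
bin, and assigning it to the post window keeps exactly 90 scored
bins and the stated 1/9 chance level. Precision =
anticipatory/(total − post); windows wrap circularly. Under uniform random
licking the expected precision is exactly 10/90, and the Monte-Carlo
check converges within 0.005 at 2·10⁴ lap draws.

## The synthetic world

Defaults state the recorded conditions rather than convenient values:
7 Hz frames (mid 6–8), ~15 cm/s running with exponential pauses below
1 cm/s, 314 cm familiar / 503 cm novel tracks (377 cm object track),
12 familiar + 15 novel laps, familiar/novel field probabilities 0.27/0.19
allocated independently (an `overlap_excess` knob plants deviations from
the product law), Gaussian fields of ~35 cm FWHM (`width_cm` is FWHM; the
Gaussian σ is width/2.355) with in-field event rates ~1.5 ev/s, novel
onset laps geometric within the first laps plus a 4-lap rate ramp,
lognormal per-lap gain jitter (σ_log 0.25; 0.6 for zone-B cells in
destabilized epochs — the planted rate-remapping effect), optional
backward COM drift, object-locked cells defined on distance-behind-object
(2–8 cm, inside the alignment window so they are detectable by
construction), a single-exponential 1.5 s calcium kernel with
instantaneous rise, additive Gaussian noise and a shared slow neuropil
component, and lick precisions of 0.40 (familiar) / 0.27 (novel)
calibrated analytically via per-bin lick probabilities.

What the generator does *not* emulate — and hence what a green test does
not establish: imaging noise spectra and motion artifacts, biophysical
calcium nonlinearity and rise time, interneurons and theta-timescale
structure, behavioral covariates beyond running speed, multi-day cell
matching, and any real-data idiosyncrasies of segmentation. Parameter
recovery on this world demonstrates the *estimators*, not the biology.

## Reproducibility and numerics

Everything is driven by explicit seeds: `simulate_session` is bit-identical
under a fixed `ScenarioConfig`; the pipeline derives per-stage seeds from
one global seed so disabling a stage never perturbs another (both
properties are tested). Floats in tidy CSVs are written with 9 significant
digits. Circular operations (distance, window, span, COM, smoothing) are
factored into one utility layer and exercised by rotation-equivariance
tests, including fields spanning the bin-1/bin-100 seam. Degenerate inputs
have defined behavior throughout: all-zero cells (SI 0 + flag, sparsity
NA, no fields), zero-variance PVs (excluded entries), empty groups and
too-short sessions (messages, never silent wrong answers).

## Known limitations

The step-2 reliability fraction is a documented default where the
criterion leaves the fraction open. Field detection on the event channel fragments sparse fields
(median-based thresholds collapse when most bins are empty), so fields are
detected on ΔF/F only. The COM estimator attenuates drift for wide fields
(see above). The object-tuning false-positive budget is nominal, not
empirical, for sparse signals. Statistical inference beyond elementary
tests (mixed-effects models, repeated-measures ANOVA) is deliberately out
of scope: the pipeline emits tidy per-cell/per-lap/per-session tables for
downstream tools.
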