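---
title: "Methods: quantifying single-neuron pattern separation and its behavioral correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying single-neuron pattern separation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patsep)
```

## The measurement model

A single dentate gyrus granule cell is driven through its perforant-path
afferents with a fixed set of five 2-s, 10 Hz Poisson spike trains,
constructed to be similar to one another (mean pairwise Pearson
correlation of their 10 ms binned counts near 0.76), and each train is
delivered ten times, giving 50 output sweeps. Because the inputs are
similar by construction, any drop from input similarity to output
similarity measures how strongly the cell separates overlapping input
patterns. The three metrics read out different neural codes:

- **Pearson R** on binned counts is insensitive to overall rate scaling
  and measures co-modulation of spike counts across bins
  (decorrelation when `R_out < R_in`).
- **NDP** (cosine similarity) measures the angle between count vectors:
  orthogonalization moves it toward 0 regardless of vector length.
- **SF** (norm ratio) isolates the rate/scaling component that R and NDP
  discard: two trains with identical shape but different spike counts
  have R = NDP = 1 but SF < 1.

For each unordered input pair the output similarity is averaged over all
10 × 10 cross-repetition sweep pairs. Same-input sweep pairs are
deliberately excluded — they measure response reliability, not
separation — and are exposed separately by `output_reliability()`.

Undefined values (zero-variance vectors for R, zero-norm vectors for
NDP/SF) are returned as `NA`, excluded from every mean, and counted in
every summary. Sparse granule-cell output makes empty sweeps common, so
silently dropping them would bias output similarity invisibly; counting
them keeps the exclusion auditable.

## Binning conventions

Bins are half-open `[kw, (k+1)w)` with 0-based indices, so a spike on an
interior edge belongs to the higher bin, and a spike at exactly the sweep
end is invalid (the validator rejects it). This removes the edge
ambiguity that a closed-interval convention would create. The bin count
is `ceiling(duration / bin_width)`; widths that do not divide the
duration leave a ragged final bin, which lets the bin-width sensitivity
sweep (5–100 ms) run on arbitrary widths. Spike times are stored in
seconds and written to CSV at 6 decimals (µs precision, finer than the
10 kHz acquisition the protocol uses), which makes write/read round-trips
exact at the declared precision.

## Group inference

ANCOVA compares the output-versus-input similarity relation between
housing groups. The headline p-value is the group main effect from the
parallel-lines model `s_output ~ s_input + group`, tested against
`s_output ~ s_input`; slope heterogeneity (`s_input:group`) is reported
separately rather than folded into one omnibus test, because the two
answer different questions (vertical offset of the relation versus change
of its gain). Per-group lines shown in figures are the separate per-group
least-squares fits. Mean outputs are additionally compared with classical
pooled-variance two-sample t-tests, mirroring standard practice when all
inputs share one similarity target; no multiple-testing correction is
applied across the three metrics, which are complementary readouts of one
recording rather than independent hypotheses.

For immediate-early-gene densities the analysis unit is the per-animal
mean density (images within an animal are pseudo-replicates), followed by
a housing × condition ANOVA with Tukey HSD on the four design cells.
Degenerate inputs follow explicit conventions: zero-variance samples with
equal means report t = 0, p = 1 (with a message); an all-equal density
table reports p = 1 throughout.

## Spike-pattern statistics

Firing rate is spikes per sweep (and Hz = count/duration). Each stimulus
opens a response window from the stimulus time to the earliest of
+50 ms, the next stimulus, or the sweep end; truncation at the next
stimulus guarantees each output spike is attributed to exactly one
stimulus. A stimulus "bursts" when ≥ 2 output spikes fall in its window
(`p_burst`), and "responds" when ≥ 1 does (`spike_probability`, the
30–80% quality-control criterion of the recording protocol). The 50 ms
cap is a package default — at 10 Hz Poisson stimulation the median
inter-stimulus interval is ~69 ms, so the cap binds most windows — and is
configurable because the underlying window choice is a convention, not a
measurement.

Compactness is the fraction of occupied bins; occupancy is spikes per
occupied bin (undefined for empty trains). Their dispersion across a
recording's sweeps is operationalized as the mean absolute pairwise
difference over sweep pairs, a direct pairwise-comparison statistic that
needs no distributional assumption; a coefficient-of-variation variant is
available via `method = "cv"`.

## The synthetic-data generators

The generators define the simulated study conditions; they are fixed
defaults, not tuning knobs.

**Correlated input trains.** A mother Poisson train at rate
`rate / p` is thinned independently into each child train with copy
probability `p`, then each copied spike receives Gaussian latency jitter
(sd 1 ms by default, making shared events asynchronous at sub-bin scale
as synaptic jitter would). Thinning was chosen because it has a
closed-form oracle: with zero jitter the expected pairwise binned-count
correlation of two children equals `p` exactly, for any bin width, which
the test suite exploits. The copy probability is calibrated by bisection
(Monte-Carlo evaluation of 200 candidate sets per probe, under a private
configuration-derived seed so calibration is a pure function of the
configuration) so that the expected mean pairwise R at the target bin
width equals 0.76; candidate sets are then rejection-sampled until the
realized mean pairwise R is within ±0.02 and every train's count is
within ±40% of `rate × duration`, with a 10,000-candidate budget before
erroring. How the original stimulation sets were constrained to their
similarity target is not documented beyond the target itself; selection
among random candidate sets is the simplest mechanism consistent with it.

**Granule-cell responder.** A phenomenological point-process responder:
each stimulus evokes a spike with probability `p_spike` (default 0.55,
centered in the 30–80% QC range) at latency 5 ± 2 ms (truncated at 0), a
doublet follows with probability 0.2 at +3 ms (a typical intra-burst
interval), background firing is Poisson at 0.2 Hz (granule cells are
nearly silent at rest), and a 2 ms absolute refractory period drops
violating spikes. Setting `p_spike = 1`, zero latency/jitter/extras/
background and zero refractory period makes the responder the identity,
which pins the analysis to the diagonal exactly — the main structural
self-check of the metric layer. The responder is deliberately not a
conductance-based neuron model: it generates the statistical structure
the analysis consumes (stimulus-locked, probabilistic, bursty, refractory
spiking), nothing more, and no attempt is made to reproduce the small
real housing-group differences, which are unrecoverable without the raw
recordings.

**Arena trajectories.** An Ornstein–Uhlenbeck velocity walk (mean mobile
speed 8 cm/s, 1 s velocity correlation time) with reflecting walls in the
40 × 40 cm arena, interrupted by rest bouts from a two-state Markov chain
with prescribed stationary rest fraction (default 20%, mean bout 2 s),
and optional constant-speed drift toward the nearest attraction point to
emulate object interest. This reproduces the features the locomotion
metrics consume — realistic speeds, immobility episodes, zone dwell —
but none of the fine structure of rodent behavior (thigmotaxis dynamics,
grooming, rearing), so passing behavioral tests validate the *metrics*,
not any behavioral model.

**Behavioral cohorts.** NOR cohorts draw per-animal discrimination
indices from a truncated normal (defaults 0.66 ± 0.10, n = 12/group —
the regime of juveniles that do discriminate; 0.5 gives a chance-level
cohort) and convert them to familiar/novel exploration times. IEG tables
draw per-image counts as Poisson(area × density) with densities set per
housing × condition cell: defaults use the sparse-recruitment regime
(home cage ≈ 0.2–0.3, post-exploration ≈ 0.4–0.6 cells/mm²), a condition
effect and zero housing effect. The cohort size (6 animals/cell, 12
images/animal, 1.5–2.5 mm² masks) was chosen once so that the built-in
condition effect is reliably detectable at these sparse densities while
staying in the range of a realistic histology experiment.

## Behavioral metric conventions

The tracking software internals (mobility threshold, center/periphery
geometry, object-zone radius) are never reported with published arena
data, so the package fixes documented defaults and makes each
configurable: mobility threshold 2 cm/s; center zone = central 50% of
each side (25% of the arena area); object zone = 4 cm radius around the
object center (a 2 cm margin around a 2 cm object proxy), with samples in
overlapping zones assigned to the nearest center. Dwell times weight each
inter-sample interval by its starting position, so center + periphery
partition the trace duration exactly. The discrimination index is
novel / (novel + familiar), undefined (and excluded, with a message) for
trials with zero total exploration.

## Numerical choices and degenerate inputs

- Near-integer `duration / bin_width` ratios are snapped to the integer
  bin count (tolerance 1e-9) so 10 ms bins on a 2 s sweep are exactly 200
  despite floating-point width representation.
- Input and output similarities are computed from one shared metric
  matrix over all binned trains of a recording, so the identity responder
  reproduces `s_output == s_input` bit-exactly rather than to rounding.
- All generators consume one seeded stream per call and attach their full
  configuration (including the seed) as metadata; the pipeline derives
  per-cell seeds from the master seed and writes seed and config-hash
  provenance columns into every table, making reruns byte-identical.
- Degenerate statistics follow the conventions listed above instead of
  erroring mid-pipeline, and every such event is logged.

## Problem sizes used in the tests

The shipped test suite exercises the full protocol at its natural size
(5 trains × 10 repetitions per cell) and uses 20 replicate cells per
condition for stochastic checks, 2000 replicates for type-I-error
calibration of the tests, 500 for the ANCOVA power check, and 2000 sets
for the thinning-correlation oracle — sizes at which the Monte-Carlo
error of each check is far below its acceptance band. The end-to-end
pipeline default of 15 recordings per housing group matches the scale of
the slice study it simulates.

## Known limitations

- The responder and generators are statistical emulators; agreement of
  simulated group summaries with recorded data is out of scope, and the
  simulated study is a true null (both housing groups share one
  responder configuration).
- Dispersion ("variation") statistics have no published closed formula;
  the mean-absolute-pairwise-difference convention here is documented so
  results can be compared against other implementations, but absolute
  values are convention-dependent.
- The ANCOVA reports the parallel-lines group effect as the headline
  test; analyses that intend the slope-heterogeneity contrast should
  read `p_interaction` instead.
- Whether the burst window of published analyses was time-based or
  count-based is not documented; the time-window definition here is a
  stated convention, configurable via `burst_window_cap`.
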