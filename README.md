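# patsep

Pattern separation — the transformation of similar input activity patterns
into dissimilar output patterns — is a core computation of the hippocampal
dentate gyrus (DG). In the slice-electrophysiology paradigm this package
analyzes, five correlated 2-s, 10 Hz Poisson spike trains are delivered to
the perforant-path afferents of a single granule cell (GC), each train ten
times, while the cell's output spikes are recorded (50 sweeps per cell).
Pattern separation is then quantified by comparing the pairwise similarity
of the input trains with the pairwise similarity of the evoked output
trains. `patsep` implements that analysis end to end for experimentalists
and modelers, together with the behavioral assays that usually accompany
it (open field, novel-object exploration and recognition,
immediate-early-gene cell counts), and a calibrated synthetic-data module
so every stage runs and is testable without recorded data.

## The similarity metrics

Spike trains are binned into count vectors (10 ms bins by default; bins are
half-open `[kw, (k+1)w)`). For two binned trains *x*, *y* the package
computes:

- **R** — Pearson's correlation coefficient of the count vectors;
  `R_output < R_input` indicates decorrelation of the incoming signal.
- **NDP** — normalized dot product, `x·y / (‖x‖‖y‖)`, the cosine of the
  angle between the count vectors; measures orthogonalization.
- **SF** — scaling factor, `min(‖x‖,‖y‖) / max(‖x‖,‖y‖)`; measures whether
  spike counts per bin are scaled up or down.

For each unordered input pair *(i, j)* the output similarity is the mean of
the metric over all cross pairs of their evoked sweeps (10 × 10 = 100
comparisons per input pair under the full protocol; sweeps of the same
input are kept apart as a separate reliability diagnostic). Points below
the identity line of output-versus-input similarity indicate pattern
separation, points above indicate convergence. Group comparisons use
ANCOVA on the similarity points plus t-tests on mean outputs; spike
patterns are further summarized by firing rate, burst probability,
compactness, occupancy and dispersion.

The synthetic input generator produces correlated Poisson trains by
thinning a common mother train with a calibrated copy probability and
rejection-samples candidate sets until the realized mean pairwise R at
10 ms bins is within ±0.02 of the protocol target 0.76.

## Worked example

```r
library(patsep)

inputs <- generate_input_set(seed = 42)     # five 2-s 10-Hz trains
inputs
#> <input_set> 5 trains, realized mean pairwise R = 0.763
#>   (copy probability 0.861, 14 rejections)

rec <- simulate_granule_cell(inputs, cell_id = "demo", group = "SH",
                             seed = 43)
rec
#> <recording_set> cell demo (SH): 5 input trains, 50 output sweeps
#>   (10 repetitions)

io <- input_output_similarity(rec, metric = "R", bin_width = 0.01)
head(io[, c("input_i", "input_j", "s_input", "s_output")], 3)
#>   input_i input_j   s_input  s_output
#> 1       1       2 0.7572860 0.3872689
#> 2       1       3 0.7374943 0.3962416
#> 3       1       4 0.7300386 0.3490819

separation_summary(io)
#> $mean_s_input            0.763
#> $mean_s_output           0.371
#> $fraction_below_diagonal 1
```

Every input pair has higher input than output correlation
(`fraction_below_diagonal = 1`): the simulated cell decorrelates its
inputs, as real granule cells do. Quality control and pattern statistics:

```r
spike_probability(rec)$probability   # 0.561 -> inside the 30-80% QC range
cell_p_burst(rec)                    # 0.134
firing_rate(rec)$mean_rate_hz        # 6.21 Hz
```

A full simulated study (15 cells per housing group, ANCOVA per metric,
t-tests on pattern statistics, figures and a text report) runs in seconds:

```r
run_patsep_pipeline("run1", seed = 42)
```

Behavioral side: `locomotion_summary()`, `zone_times()`,
`object_exploration_time()` on tracking traces; `discrimination_index()`
with `one_sample_t(di, 0.5)` for novel-object recognition; `ieg_density()`
with `two_way_anova_tukey()` for cFOS/NPAS4 cell densities.

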