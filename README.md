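# scnburst

Burst firing and circadian rhythm analysis for suprachiasmatic nucleus (SCN)
recordings.

Cultured SCN slices recorded on multi-electrode arrays normally show a smooth
circadian modulation of multiunit firing (roughly 2–18 Hz at the circadian
peak). When GABA signaling is disrupted, that rhythm persists but is overlaid
with slice-wide synchronous *burst firings* — a few seconds of 35–80 Hz
activity recurring every 2–3 minutes, at all circadian phases — accompanied
by large calcium transients, while the molecular clock (PER2 reporter
rhythms) stays intact. `scnburst` implements the full analysis chain for
characterizing this phenotype, for electrophysiologists and chronobiologists
working with slice or behavioral recordings:

- **Spike trains**: rate binning, the operational burst definition (a 100-ms
  bin above 35 Hz), bin-ratio distributions, burst-event catalogs, two-band
  decomposition of the 1-min rhythm, pairwise synchrony matrices, and burst
  phase profiles in circadian time.
- **Rhythms**: chi-square (Sokolove–Bushell) periodogram
  (Qp with a pointwise p < 0.01 significance line), cosinor fits (mesor M,
  amplitude A, acrophase φ of `M + A·cos(2π(t − φ)/τ)`), Rayleigh circular
  statistics (mean vector length r), standardized amplitude
  `(peak − trough)/peak` and damping ratio, and circadian-time conversion
  anchored at CT12 := PER2 peak.
- **Imaging**: per-pixel acrophase maps of bioluminescence stacks, line-scan
  kymographs, ROI series, calcium-transient detection (running-median dF/F,
  4-MAD threshold), and burst–calcium coincidence fractions.
- **Behavior**: actogram activity-onset detection, cycle-to-cycle onset
  variability, daily profiles, light/dark activity partition, free-running
  period.
- **Synthetic data**: generators that emulate wild-type and GABA-deficient
  recordings (spike trains, burst schedules, reporter image stacks, calcium
  traces, actograms) from a single seed, so the whole pipeline is testable
  without raw data.

Everything is tidyverse-native: tabular inputs and outputs are tibbles,
fitted objects have `tidy()`/`glance()` methods, result types have
`autoplot()` methods, and `run_pipeline()` ties the stages together into a
manifest-tracked run.

## Worked example

Simulate a GABA-deficient slice for one hour, apply the burst definition in a
10-min window at the circadian peak, catalog events, and measure synchrony:

```r
library(scnburst)

cfg      <- gen_config("gaba_deficient", duration_h = 1, n_electrodes = 6, seed = 42)
schedule <- gen_burst_schedule(cfg)
trains   <- gen_spike_trains(cfg, schedule)
rates    <- bin_spikes(trains, 0.1)          # 100-ms bins

bin_ratio_distribution(rates, window = c(0, 600))
#> <bin_ratio_distribution> 36000 bins; 3.336% above 35 Hz

glance(detect_bursts(rates))
#> # A tibble: 1 × 4
#>   n_events n_merged threshold_hz median_interval_s
#>      <int>    <int>        <dbl>             <dbl>
#> 1      150       25           35              142.

synchrony_matrix(rates, window = c(0, 600))
#> <correlation_matrix> 6 electrodes; mean off-diagonal 0.603
```

More than 3% of 100-ms bins exceed the 35-Hz burst criterion (a wild-type
run, `gen_config("wt", ...)`, gives exactly 0% — its 35-ms refractory period
caps bins at 30 Hz). The 150 per-electrode events merge into 25 slice-level
events — the same burst seen on all six electrodes — recurring with a median
interval of ~142 s, and the shared bursts drive the mean pairwise correlation
to 0.60, far above the near-zero value of independent wild-type electrodes.

`autoplot()` works on the intermediate objects (periodograms, bin-ratio
distributions, synchrony matrices, acrophase maps, kymographs), and
`plot_actogram()` double-plots behavioral records.

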