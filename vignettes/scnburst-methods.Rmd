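---
title: "Models and methods behind scnburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scnburst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

The suprachiasmatic nucleus (SCN) is the master circadian pacemaker. In
multi-electrode recordings of cultured SCN slices, wild-type tissue shows a
smooth sinusoidal circadian modulation of multiunit firing, typically between
about 2 Hz at the circadian trough and 18 Hz at the peak. When GABA signaling
is absent, the same circadian rhythm persists but is overlaid with brief,
high-frequency burst events (35–80 Hz) lasting a few seconds, recurring every
2–3 minutes, synchronized across the whole slice, and occurring at all
circadian phases. Molecular clock rhythms (a PER2 bioluminescence reporter)
remain intact, and behavioral rhythms of animals with reduced SCN GABA
signaling show increased cycle-to-cycle onset variability and reduced
periodogram power without a change in free-running period.

`scnburst` implements the complete analysis chain behind these observations —
burst statistics on spike trains, synchrony matrices, rhythm statistics,
pixel-level acrophase maps, calcium-transient coincidence, and actogram
analytics — together with a synthetic-data generator that reproduces the
statistical structure of both genotypes, so that every stage can be validated
end to end without access to raw recordings.

## The operational burst definition

Firing rates are computed in left-closed, right-open bins; the trailing
partial bin is dropped, so counts are deterministic (a 10-min record in
100-ms bins is exactly 6000 bins). The burst criterion is applied to 100-ms
bins: a bin with a rate above 35 Hz is a burst bin. The *bin-ratio
distribution* (`bin_ratio_distribution()`) is the histogram of 100-ms bin
rates pooled over on-SCN electrodes, expressed as the percentage of bins per
frequency class; `frac_above_pct` summarizes the supra-35-Hz mass. In
wild-type-like data the refractory period caps the achievable bin rate below
the criterion, so this fraction is exactly zero; in GABA-deficient data it
exceeds 3%.

`detect_bursts()` segments supra-threshold bins into events: maximal runs of
burst bins, with runs separated by at most `merge_gap_s` fused into one
event. The threshold is the field's operational definition; event
segmentation is our own convention, and the default `merge_gap_s = 0.5` s
reflects that bursts last seconds, so sub-second dips belong to the same
event. Both per-electrode and slice-merged catalogs are returned; the merged
catalog is the natural object for a phenomenon that is synchronized across
electrodes.

## Synchrony and phase dependence

`synchrony_matrix()` computes Pearson correlations between the 100-ms rate
series of all on-SCN electrode pairs in a window (convention: 10 min at CT8,
the phase of maximal firing). Electrodes with zero variance in the window
yield undefined pairs, excluded from the off-diagonal mean. The estimator and
bin width are declared defaults — the source analyses name neither.

`burst_phase_profile()` counts burst bins in 10-min windows centered at every
4 circadian hours, averages across cycles, and divides by the daily mean
count, so a phase-independent burst process gives a flat profile at 1.
Windows are *centered* on each CT mark (a declared choice; anchoring at the
window start would shift the profile by 5 min, immaterial at 4-h spacing).
Circadian time is anchored by `to_ct()`: CT12 is the PER2 reporter peak, and
the generator places the firing peak at CT8, consistent with peak multiunit
activity at CT8.

## Rhythm statistics

**Chi-square periodogram.** `chisq_periodogram()` uses the Sokolove–Bushell
statistic: the series is folded at each candidate period P (in samples),
`Qp = N · Var(column means) / Var(series)` over the `N = floor(n/P)·P`
retained samples, with the pointwise significance line
`qchisq(1 - alpha, P - 1)` and no multiplicity correction (matching the
oblique line of standard periodogram plots). The period grid spans 20–28 h at
one sample per step (1-min bins for behavior and firing, 10-min for reporter
traces). One numerical subtlety: on low-noise series spanning few cycles the
Qp peak is a broad plateau, and because raw Qp scales with the retained
sample count N(P), its argmax drifts toward longer periods (on a noiseless
23.86-h cosine sampled for 5 cycles the raw argmax lands at 24.0 h). The
best period is therefore chosen among supra-line periods as the argmax of the
normalized ratio Qp/N — the fraction of variance carried by the folded
waveform — which sits exactly on the true grid period for noiseless cosines
and is what the package reports as `best_period_h`. A series with no
supra-line period (or zero variance) is flagged `arrhythmic`.

**Cosinor.** `cosinor_fit()` fits `M + A·cos(2π(t − φ)/τ)` by least squares.
With τ fixed this is the closed-form regression on cosine and sine
regressors (the package's test suite checks exact agreement with `lm()` on
those regressors); with τ free, the residual sum of squares is profiled on a
0.05-h grid over 20–28 h and refined with `optimize()`. The acrophase is the
fitted peak time wrapped to `[0, τ)`. The exact fitting variant (detrending,
weighting) of the original software is unspecified; unweighted least squares
on the raw series is our declared choice.

**Rayleigh statistics.** `rayleigh_stats()` maps phases to angles
`θ = 2π·phase/τ` and reports the circular mean and the mean vector length
`r = |Σe^{iθ}|/n`; r is invariant under common rotation and equals 1 for
perfect synchrony, 0 for uniform or symmetric dispersion.

**Amplitude and damping.** `amplitude_metrics()` smooths with a centered
2-h moving average (long enough to remove burst-band contamination from 1-min
rate series, short enough not to shift circadian phase materially), cuts the
series into consecutive cycles of length τ, and computes the standardized
amplitude `(peak − trough)/peak` per cycle. The damping ratio is the
standardized amplitude of cycle 6 divided by that of cycle 1 — a declared
convention for the "first six cycles" summary, which the source does not
define formally. On a noiseless trace with per-cycle damping factor d, the
estimate equals the closed form implied by the generator model and approaches
d^5 when the amplitude is small relative to the mesor.

## Imaging

`pixel_acrophase_map()` fits the fixed-τ cosinor to every pixel trace in one
linear-algebra pass (a single slice-level τ stabilizes per-pixel fits and
matches how acrophase maps are used); pixels explaining less than 10% of
variance (configurable) are masked as non-rhythmic — the exclusion criterion
for Rayleigh plots is not stated in the source, so this is a declared
default. The relative map subtracts the circular mean phase of masked-in
pixels, wrapped to `(−τ/2, τ/2]`. Time-shift equivariance (shifting frame
times by Δ shifts all acrophases by Δ and leaves the relative map unchanged)
is enforced by construction and covered by tests.

`line_scan()` samples intensity along a pixel path per frame (row 1 is
dorsal, fixing the dorsal-to-ventral orientation of kymographs);
`roi_series()` averages frames over a mask. `detect_ca_spikes()`
baseline-corrects each calcium trace with a running median (window 60 s by
default, at least ten times a typical transient; the trace is reflect-padded
so events at the edges keep a robust local baseline), defines dF/F residuals
against that baseline (calcium normalization is not defined in the source),
and flags contiguous runs of samples exceeding k = 4 noise SDs. The noise
scale is estimated robustly from first differences
(`mad(diff(x))/sqrt(2)`, immune to the baseline and to sparse transients)
and inflated by `sqrt(1 + pi/(2m))` to match the null SD of a
median-subtracted residual (m the window length). So calibrated, Gaussian
noise yields fewer than one false event per 24 h of 3-s frames. `burst_ca_coincidence()` reports, both ways, the
fraction of event onsets within a tolerance of an event of the other
catalog; the pipeline default tolerance is the calcium frame interval, since
onset times are quantized to frames.

## Behavior

`detect_onsets()` uses a 6 h/6 h contrast template: the onset of a cycle is
the earliest minute maximizing mean activity in the following 6 h minus the
preceding 6 h, searched within ±6 h of the expected onset (previous onset
plus the period guess; the first cycle is searched globally). This template
is a declared, configurable stand-in for the unpublished commercial
algorithm. Cycles without activity contribute no onset and are excluded.
Regressing onset on cycle index yields the free-running period (slope) and
the cycle-to-cycle variability (residual SD in minutes), which recovers an
injected 20-min onset jitter without material bias at 28 cycles.
`daily_profile()` folds activity at the period into 2-h bins;
`activity_partition()` splits counts by light state under LD, or by
subjective night (12 h from each onset, consistent with nocturnality) under
DD. `behavior_period()` delegates to the periodogram on the trailing 28 days
of 1-min counts.

## The synthetic-data generator

The generator (`gen_config()` plus `gen_*()`) encodes the study conditions:

* **Baseline spiking** is a renewal process with an absolute refractory
  period (default 35 ms) followed by an exponential wait whose hazard is set
  so the mean inter-spike interval equals the reciprocal of the target rate;
  the target rate is a sinusoid between 2 and 18 Hz (defaults) with period
  23.86 h for the wild-type preset and 23.63 h for the GABA-deficient preset
  (the two genotype means). The hazard is refreshed every 60 s — against a
  ~24-h modulation this piecewise-stationary approximation is negligible.
  The 35-ms refractory makes more than 3 spikes per 100-ms window impossible,
  so wild-type bins are capped at 30 Hz, strictly below the 35-Hz criterion.
* **Bursts** (GABA-deficient preset) follow a slice-wide schedule: start-to-
  start gaps i.i.d. uniform on [120, 180] s, each event lasting 5 s, starting
  at t = 0 and covering the record, so event timing is tied to elapsed time,
  not circadian phase. During events all electrodes spike *regularly* at the
  burst rate (default 60 Hz, admissible 35–80 Hz): regular spiking makes
  every fully-inside bin carry exactly `rate/10` spikes, so the 35-Hz
  criterion is exactly testable. Intra-burst spike statistics and the exact
  burst duration are not specified by the source ("a few seconds"); these
  are declared defaults.
* **Reporter image stacks**: pixel i emits
  `M + A·d^(t/τ)·cos(2π(t − φ_i)/τ) + noise` with per-pixel acrophases
  wrapped-normal around the slice PER2 peak (SD default 0.5 h, emulating the
  tight phase dispersion of intact slices), hourly frames, damping d = 0.95
  per cycle.
* **Calcium traces**: circadian baseline plus a transient (one-frame rise,
  5-s exponential decay) at every schedule event, amplitude at least five
  times the noise SD, sampled at 3-s frames (0.33 fps).
* **Actograms**: square-wave nocturnal activity (active half the period),
  onsets perturbed by N(0, `onset_jitter_min`), Poisson count noise, 1-min
  bins, with an optional 12:12 LD annotation.

All randomness derives from one seed through a fixed splitting scheme
(documented in the source), so every generator is bit-reproducible and
per-electrode output is invariant to the number of electrodes requested.

What the generator does *not* emulate: biophysical membrane dynamics, GABA
receptor kinetics, optical point-spread functions, photobleaching, electrode
geometry, spike-sorting noise, or drift in firing rate across culture days.
Passing tests therefore demonstrate that the analysis chain implements its
definitions correctly and recovers known parameters under the stated
statistical structure — not that it is robust to every artifact of real
recordings.

## Problem sizes and numerical choices

The validation suite exercises the pipeline at the scale of the study
conditions where the quantity depends on it — e.g. the wild-type ceiling and
period recovery run 12 electrodes for 5 circadian cycles (about 50 million
spikes), onset-jitter recovery uses 28 cycles and 20 replicates, and the
synchrony ordering uses 40 matched seed pairs — and at reduced scale where
only the operational definition matters (single electrodes, 10-min windows).
Ties in onset detection resolve to the earliest maximum; bins are
left-closed; a trailing partial bin or cycle is dropped; degenerate inputs
(constant series, empty schedules, zero-variance electrodes, empty event
lists) return flagged results rather than errors wherever the quantity is
defined to be absent.

## Known limitations

* The periodogram's chi-square null is approximate for autocorrelated
  series; the significance line is calibrated for white noise (the suite
  checks the pointwise false-positive rate on that null).
* Free-τ cosinor profiling assumes a single dominant period in 20–28 h.
* The onset template assumes a consolidated active phase; fragmented
  activity may need different template widths.
* Coincidence fractions compare event onsets only, not durations or shapes.
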