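---
title: "Methods: cross-state analysis of auditory population codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-state analysis of auditory population codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators and design choices behind
`soundstates`. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The scientific problem

Anesthesia drastically lowers spontaneous firing in early auditory
structures, and single neurons tracked across wakefulness and anesthesia can
lose, gain, or invert their sound responses even when population summaries
(tuning-width averages, overall decoding accuracy) change little. Detecting
this requires comparing representations *in the same neurons* across states:
matching units across separately sorted recordings, decoding sound identity
within and across states, and asking whether the two states' responses
occupy the same region of population-activity space. Every stage of that
analysis has failure modes, so the package pairs the analysis code with a
synthetic two-state world in which ground truth is known and each estimator
can be validated end to end.

## Stimulus battery and session

The battery holds 307 short sounds in 8 categories with fixed counts
(pure tones 28, intensity ramps 26, chords 48, chirps 20, band-passed noises
30, AM sounds 48, complex 60, decomposition 47). Pure tones sit on a
14-point log grid between 2 and 60 kHz at 50 and 70 dB SPL; ramps sweep
50-70 dB over 500 ms at the 13 grid frequencies below 50 kHz; AM sounds use
6 modulation frequencies between 4 and 160 Hz by 8 carriers. Where only
counts and ranges are specified (exact chord and noise-band frequencies,
chirp ranges, complex-sound content), values are drawn once per seed inside
the stated ranges. "Complex" and "decomposition" sounds are band-limited
multi-component envelopes with smooth seeded temporal shapes; for decoding
and simulation only their identity and spectral support matter.

A session repeats each sound 12 times in seeded random order in 123 blocks
of 30 trials (the last block holds 24, since 307 x 12 = 3684 = 122 x 30 +
24) with 1-s onset spacing; 20 natural 30-s segments are interleaved at 20
distinct inter-block positions; consecutive segments are separated by
>= 3-s silent gaps, giving 142 gaps. The session starts with a 1-s lead-in
so the first trial's baseline window is recorded. All times are seconds
from session start; intervals are half-open `[start, end)`.

## Ground-truth neuron model

Each unit has, per state: spontaneous rate, best frequency (BF), tuning
half-width, signed peak gain, intensity threshold, and a 5-ms latency. The
driven rate for a sound is

    rate(t) = max(0, spont + gain * F(f) * G(L(t)) * E(t))

* `F` — Gaussian tuning in log2 frequency. The parameter `hw` is the **full**
  half-width, `log2(f_above/f_below)` between the two half-maximum
  frequencies — exactly the quantity the half-width estimator reports — so
  `F` falls to 1/2 at `hw/2` octaves either side of BF. (Two plausible
  conventions exist, per-side HWHM versus full width; the full-width
  convention was chosen so the estimator's analytic target equals the
  parameter.)
* `G` — a soft intensity gate `plogis((L - threshold)/1.25)`, a ~5-dB
  sigmoid edge. A hard gate would make the ramp-threshold estimator's
  crossing time degenerate; the soft edge gives it a well-defined crossing
  at the cost of a small systematic early bias (the response becomes
  detectable slightly below the nominal threshold), visible in the
  recovery test.
* `E` — the temporal envelope: 10-ms cosine onset/offset ramps, sinusoidal
  modulation for AM sounds, the stored envelope for complex sounds, the
  level trajectory for intensity ramps, and the instantaneous sweep
  frequency for chirps.

Spiking is inhomogeneous Poisson. Session simulation uses exact
superposition/thinning: a homogeneous spontaneous process over the session,
plus Poisson counts for the positive part of the drive, with spontaneous
spikes thinned bin-wise where rectified rates fall below the spontaneous
rate. Sounds contributing < 0.05 spk/s at their peak for a given unit are
skipped (< 0.02 expected spikes over 12 trials).

### Default parameters (the stated world)

| parameter | default | why |
|---|---|---|
| wake spontaneous rate | log-normal, median 4 spk/s, capped at 100 | observed range 0 to ~100 spk/s |
| anesthesia spontaneous | wake x U(0.05, 0.5); 0 if silenced | strong reduction under anesthesia |
| silenced fraction | 0.40 | between the reported 32% and 47% |
| remodeling class probs | (24, 34, 35, 36)/129 | reported decrease/increase/sign-change/no-change fractions |
| peak gain | U(40, 90) spk/s | high-rate early auditory neurons |
| best frequency | drawn on the 14-point probe grid | the recovery contract targets the nearest grid frequency; off-grid BFs near bin midpoints make "exact" recovery ill-defined |
| tuning half-width (wake) | U(0.4, 0.8) octaves | see below |
| anesthesia half-width | wake x U(0.6, 0.95) | narrower tuning under anesthesia |
| threshold | U(45, 60) dB, +U(0, 5) under anesthesia | slight threshold elevation |
| latency | 5 ms | not constrained by data; documented default |
| tone duration | 0.3 s | battery constraint (< 0.5 s), enough driven spikes for 12-trial estimates |

The half-width range sits slightly below typical *estimated* population
means (~0.5-1.1 octaves): the estimator applied to noisy 14-point tuning
curves is biased upward, and a power analysis (run before freezing the
defaults) showed that widths >= 1 octave put adjacent-grid-bin response
differences below Poisson noise at 12 trials, which would make the
best-frequency recovery contract unattainable in principle. The SNR regime
is therefore part of the stated world, chosen once.

What the generator does **not** emulate: non-Poisson spiking (bursting,
refractoriness), adaptation, trial-to-trial rate correlations, electrode
drift, spike-sorting errors, and onset-vs-sustained response typology. A
green test therefore establishes estimator correctness under the stated
statistical model, not robustness to those real-data features.

## Estimators and numerical choices

* **MAD** — `median(|V - median(V)|)`, deliberately without the 1.4826
  Gaussian-consistency factor: the defining formula omits it. For Gaussian
  noise the estimate converges to 0.6745 sigma; tests assert that identity
  rather than unscaled SD.
* **Response tensor** — 10-ms bins on [-0.3, 1] s, per-trial mean baseline
  (-0.3 to 0 s) subtracted. A cheap `extract_rate_tensor()` variant keeps
  only the per-trial time-averaged rate during the sound; all downstream
  code accepts either.
* **Best frequency** — maximal mean response; ties break toward the lower
  frequency. For classification contexts the absolute response is maximized
  so suppressed units get a BF; the plain signed maximum is the default.
* **Half-width** — on `|r|` versus log2 f, walking from the peak to the
  nearest half-maximum crossing on each side (contiguity enforced), linear
  interpolation between grid points; a side that never crosses is censored
  at the grid edge and flagged. Interpolating a curved flank on the
  0.262-octave grid is accurate to ~0.04 octaves.
* **Ramp threshold** — first bin at `t >= 0` where the trial-averaged
  baseline-subtracted rate exceeds 2 SD of the baseline-bin distribution
  (the *text* rule; the printed comparison direction is inverted and was
  not followed); the bin's left edge maps to level via `50 + 20 t / 0.5`.
  Zero baseline SD falls back to a tiny floor. The 2-SD rule on 10-ms
  trial-averaged bins false-alarms at ~2% per bin, so recovery tests use
  50-ms analysis bins.
* **Response-change classes** — two-sided Mann-Whitney at alpha = 0.05,
  uncorrected (matching per-unit usage): each state versus its pooled
  baseline sample first (neither significant: nonresponsive; both,
  opposite signs: sign change), then wake versus anesthesia responses
  (decrease / increase / no change). The null sample for the
  versus-zero test is the mean-centred baseline distribution of the same
  trials; the reference analysis does not specify this choice.
* **Matching** — Pearson correlation of flattened templates (configurable
  channel window centred on the peak channel); the chance null is, per wake
  template, the maximal correlation with other-recording anesthesia
  templates, thresholded at its 95th percentile; candidates with a
  same-recording competitor within 0.2 are rejected as ambiguous; a
  mutual-best filter enforces one-to-one pairs (the directional rule alone
  can let one anesthesia unit claim two wake units).
* **Decoder** — per split, train vectors are per-sound means over a random
  half of trials (odd counts put the extra trial in training) and test
  vectors over the complement; prediction is the train sound with maximal
  Pearson correlation; zero-variance vectors get correlation -Inf; ties
  break to the lowest sound index. Cross-state designs train on one state's
  half and test on the other's complementary half, in both directions; the
  summary is their mean. SEM is reported over sounds (the alternative,
  over splits, is noted as ambiguous in the source description).
* **Bootstrap** — neurons resampled with replacement independently per
  state, 100 populations by default, 50 splits each; the one-sided p per
  category is the fraction of bootstrap differences on the opposite side of
  zero from the mean.
* **State space** — PCA on all (sound, state) trial- and time-averaged
  vectors jointly (fitting states separately would manufacture separation),
  mean-centred, unscaled (responses share units of spk/s). The state
  classifier is a linear hinge-loss maximum-margin machine at C = 1 solved
  by dual coordinate descent on internally standardized features (no
  external SVM dependency is available offline); folds partition *sounds*,
  so every fold holds both states of its sounds (1:1 state ratio).
  Rotation to the boundary maps the 2-PC plane onto (normal, collinear)
  axes of the decision line; an exact isometry.

## Known limitations

* The decoder and state-space analyses assume rectangular tensors (equal
  trial counts per sound); dropped trials drop the whole sound.
* The chance-null threshold needs >= 2 recordings; single-recording data
  must supply an explicit threshold (e.g. the published 0.74).
* The internal SVM is adequate for the small PC-space problems it serves;
  it is not a general-purpose SVM.
* Simulated waveform diversity is finite (multi-lobe parametric family), so
  chance template correlations are higher than for real heterogeneous
  units; the empirical null absorbs this, at the cost of conservative
  match recall — mirroring the stringency of the published criteria, which
  matched only a small fraction of units.
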