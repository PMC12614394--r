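---
title: "Time-frame dynamics of tapping and voice in Parkinson disease: model, generator and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-frame dynamics of tapping and voice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapvoice)
```

## The problem

Bradykinesia and hypokinetic dysarthria in Parkinson disease (PD) are
usually summarised by whole-task averages: total taps in 20 s, mean jitter
over a 10 s vowel. Those averages discard the *within-task trajectory* —
whether performance is stable or degrades over a few seconds — which is
where fatigue-like dynamics and their dependence on disease severity live.
This package analyses short smartphone tasks by splitting every recording
into five equal time frames (TFs) and modelling the per-frame features as a
function of time, group, and severity.

Tasks and frames:

| task | duration | frame width | per-frame features |
|---|---|---|---|
| alternating finger tapping | 20 s | 4 s | inter-tap interval SD |
| sustained /a/, /i/ | 10 s | 2 s | loudness, jitter, shimmer |
| /dadada/, /pa-ta-ka/ | 5 s | 1 s | inter-onset interval SD |

Frames are half-open `[start, end)`; the printed ranges ("0 s–4 s,
4 s–8 s") are only non-overlapping under that reading, and the trial-end
instant is folded into TF5. An inter-tap or inter-onset interval belongs to
the frame containing its *later* event — the single-valued, causal choice;
the protocol is silent on straddling intervals.

## Feature definitions

* **Tap variability.** Taps are filtered to strict alternation: a tap is
  kept iff its side differs from the previously *kept* tap (the first is
  always kept). An excluded same-side press therefore bridges its
  neighbours into one longer interval, keeping the interval series gap-free;
  the stricter reading that discards any interval spanning an excluded tap
  is available as `tap_summary(..., bridge_excluded = FALSE)`. The
  feature is the sample SD (n−1) of intervals per frame; the whole-trial
  "mean variability" is the mean of the five per-frame SDs.
* **Loudness.** Short-time intensity (25 ms windows, 10 ms hop) compressed
  with the Stevens exponent: `loudness = intensity^0.3` (= RMS^0.6), so
  doubling amplitude multiplies loudness by 2^0.6. This is an energy proxy
  for the toolkit-defined perceptual loudness used in the original
  measurements; only relative within-trial dynamics enter the analysis.
* **Jitter / shimmer (local, relative).** Cycle marks are found by
  peak-picking at the period suggested by an autocorrelation F0 track
  (40 ms frames, 75–500 Hz, voicing threshold 0.45), then refined to
  sub-sample precision by cross-correlating each cycle against the trial's
  average cycle shape. Jitter = mean |T_i − T_{i−1}| / mean T; shimmer is
  the same functional on per-cycle peak amplitudes (read off a lightly
  smoothed waveform; the smoothing attenuation cancels in the ratio).
  "Jitter/shimmer variability" is the coefficient of variation (sample
  SD / mean) of the five per-frame values of a trial — the only per-trial
  series the design defines.
* **Syllable timing.** Onsets are upward crossings of the 20 ms energy
  envelope at 0.2 × its 95th percentile, confirmed by a rapid climb past
  2.5 × the threshold within 12 ms (which rejects ripple on decaying burst
  tails), with an 80 ms minimum gap. Repeat count = number of onsets;
  variability = SD of inter-onset intervals, overall and per frame. The
  original study does not describe its onset method; this detector is a
  documented substitute validated against generator truth.

## Statistical battery

Group contrasts use the pooled-variance two-sample t test on per-subject
means (features are computed per trial — 2 sessions × 2 hands for tapping,
2 × 3 trials per vocal task — and averaged within subject first), matching
the df = 38 convention for 20 + 20 subjects. The time course within a group
is tested by a one-way repeated-measures ANOVA over TF1–TF5 plus paired
post hoc t tests of each frame against TF1 with Holm adjustment.

The central models are linear mixed models with a random intercept per
subject, REML, on one row per subject × trial × frame:

* time × group: `value ~ tf + group + tf:group`, control = 0, PD = 1;
* time × severity (PD only): `value ~ tf + updrs3 + tf:updrs3`, UPDRS III
  uncentered (a centering switch exists but is off, so intercepts refer to
  UPDRS = 0 as in the published tables).

TF enters the mixed models as numeric 1..5 — the published models report a
single "time frame" coefficient — while the ANOVA treats TF as categorical.
Only a random intercept is used: the published df pattern (38 for the
two-group models, 19 within PD) indicates subject-level clustering without
random slopes. Inference uses Satterthwaite degrees of freedom
(`lmerTest`), which simulation shows is well calibrated here; the published
SPSS-style df conventions (n−2 / n−1) are emitted alongside as `df_paper`
for table comparability. Wald 95% CIs use the Satterthwaite df. Singular
fits (variance at the boundary) are flagged, not refitted: at the boundary
the GLS solution already coincides with OLS. No multiplicity adjustment is
applied across features by default (the source analysis used α = .05 per
test); Benjamini–Hochberg is available behind `adjust = "BH"`.

Severity association is also summarised marginally: Pearson r between
feature values (pooled over trials and frames) and UPDRS III, with R² = r².

## The synthetic cohort: what it emulates

No participant data accompany the study, so validation is
simulation-based, with the generator reproducing the *statistical
structure* the analysis assumes — not human physiology. It has two tiers
that share one ground-truth object.

**Signal tier** (what the extractors see):

* *Taps.* Lognormal inter-tap intervals; control mean 0.25 s (~80
  alternating taps per 20 s hand), PD mean 0.35 + 0.009·UPDRS (~0.55 s at
  the cohort mean — the published count scale). Within frame k the interval
  SD is σ0 + slope·(k−1); σ0 ≈ 0.024 for controls and 0.030 + 0.0032·UPDRS
  for PD, slopes 0.002 and 0.002 + 0.00035·UPDRS — anchored to the
  published TF1→TF5 progression (0.0238→0.0323 control, 0.101→0.143 PD).
  2% of events duplicate the previous side, placed strictly between their
  neighbours, so the alternation filter is exercised and its output is
  checkable against the injected set.
* *Phonation.* Harmonic cycles (subject F0 150–220 Hz snapped to the sample
  grid; two fixed resonances per vowel, unit-peak shape) with per-cycle
  multiplicative period and amplitude perturbations scaled so the *local*
  jitter/shimmer in frame k equals base + slope·(k−1); amplitude follows a
  piecewise-linear envelope anchored at each cycle's waveform peak, so the
  injected per-cycle amplitude is exactly what a peak-reading extractor
  should recover. White noise at 30 dB SNR. With all perturbations zero and
  noise off the output is exactly periodic at sample resolution — the
  estimator-zero test case.
* *Syllable trains.* 120 ms bursts with 8 ms attacks; inter-onset intervals
  normal with control mean 125 ms (≈40 repeats) and PD mean
  132 + 0.4·UPDRS ms, SD 8 ms (control) vs 8 + 0.6·UPDRS ms (PD),
  truncated so bursts never overlap; noise at 20 dB SNR; true onsets are
  exported.

**Feature tier** (what the inference suites consume). Calibration of the
interaction test needs hundreds of cohorts; synthesising and re-analysing
audio for each would dominate runtime without informing the inference
question. `simulate_feature_table()` therefore draws per-trial per-frame
feature values directly from the generating linear model: for PD,
`b0 + b_tf·tf + b_sev·UPDRS + b_int·tf·UPDRS + subject intercept + noise`,
with the fixed effects set to the published interaction-model coefficients
(these reproduce the published PD group means almost exactly when evaluated
at UPDRS 22.1 and TF 3 — an internal-consistency check of the published
tables that this package's tests re-verify numerically). Controls sit at
the published control means with a flat time course. Between-subject SDs
are derived, not tuned: they are chosen so the analytic z of each group
contrast equals the published |t| (floored at 3 where the published
contrast was weaker, since the direction suite requires a joint event over
~20 contrasts). Within-trial dispersion is larger in PD for jitter/shimmer
(30% vs 17% relative), which is what carries the elevated PD
jitter/shimmer CV. Strictly positive features are floored and their random
intercepts bounded at ±2 SD — CVs degenerate when a simulated mean
approaches zero, a pathology of unbounded normals rather than of voices.

Scenario `null_interaction` zeroes every severity coupling (interaction
*and* main effect), making the generating distribution of each feature
identical across UPDRS conditional on frame — the regime in which the
interaction test's rejection rate should be its nominal α.

The signal tier is validated against its own truth (recovery suites); the
feature tier carries the inference suites; tapping, being cheap, goes
through the full signal chain everywhere. What passing tests do *not* show:
robustness to real-world recording conditions (room noise, device
variation, dysphonia beyond mild aperiodicity), to non-linear severity
couplings, or to tap patterns other than alternation-with-duplicates.

## Numerical choices and edge cases

* Seeds: one master seed; each trial's RNG substream is derived by hashing
  (subject, task, trial) with FNV-1a, so any single trial regenerates
  identically in isolation (a full byte-for-byte run under a fixed seed is
  a test).
* Frames with fewer than two intervals/cycles yield `NA`, and whole-trial
  aggregates average over the available frames; an unvoiced phonation trial
  yields all-`NA` phonation features.
* The exact zero-variance ANOVA case (all frames identical within subject)
  is reported as F = 0, p = 1 — no evidence of a time effect — rather than
  0/0.
* A constant severity covariate makes both severity terms inestimable and
  errors out rather than silently dropping terms.
* The group-contrast table marks the pa-ta-ka interval-variability row as
  not direction-scored: that contrast is essentially null in the source
  data (t = −0.10), so its sign is reported but carries no expectation.
* The PD tapping time-course check is the sign of the fitted linear slope
  across the five per-frame means. Requiring every adjacent pair of
  estimated means to be ordered is not a property the protocol's own
  sampling noise supports: with ~7 intervals per 4 s PD frame, per-frame SD
  estimates carry ~30% relative noise and strict monotonicity of five noisy
  means holds in only ~60% of cohorts even though every expected difference
  is positive. The report emits both the slope and the strict `monotone`
  flag.

## Validation sizes

The acceptance suite uses: 1,000 random logs
for the filter oracle; 30 replicates per injected jitter/shimmer level
(±20% tolerance, ≤1e−6 for the unperturbed case); 50 syllable trains
(exact counts, interval SD within 10%); 500 null cohorts for type-I error
(3–8% band at α = .05) and 500 paper-like cohorts for 95% CI coverage
(92–98%); 200 cohorts for interaction sign (≥90% per feature) and bias
(≤10%); 100 cohorts for joint direction agreement of the scored group
contrasts (≥90%). These sizes put Monte-Carlo error comfortably inside
each band while keeping a full run in the tens of minutes on one core.
`scripts/acceptance.R` recomputes the same quantities with somewhat leaner
replicate counts (300/120/60 for the three simulation suites) so that one
scripted run stays within a few minutes of the test suite's heaviest block.

## Limitations

The generator's severity couplings are linear by construction, matching the
linear interaction terms being estimated — recovery results say the chain
estimates what was injected, not that real PD dynamics are linear. Vocal
feature *levels* for the speech tasks sit on an arbitrary scale (the source
tables print variability on an unstated unit); directions and interaction
signs, not levels, are the anchored quantities. The DSP is deliberately
minimal — no formant tracking, no harmonics-to-noise ratio, no speaker
normalisation — and the loudness proxy is an energy compression, not a
perceptual model. Hands are averaged within subject (the protocol does not
state whether hands were pooled); sessions enter the mixed models as
repeated trials.
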