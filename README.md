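# tapvoice

Dynamic, time-resolved analysis of smartphone-based motor and vocal
assessments for Parkinson disease (PD).

Short smartphone tasks — 20 s of alternating two-finger tapping, 10 s
sustained vowels (/a/, /i/), and 5 s rapid syllable repetition (/dadada/,
/pa-ta-ka/) — carry more information than their whole-trial averages: how
performance *changes within the task* tracks disease severity. `tapvoice`
implements the full chain for that analysis:

1. **Synthetic cohort generator.** Simulated subjects (default 20 PD / 20
   controls; UPDRS part III ~ N(22.1, 10.64²) truncated to [5, 60]) with
   known ground truth: tap-event logs whose inter-tap-interval SD grows over
   the trial, harmonic vowel audio with injected cycle-level jitter and
   shimmer and a loudness drift, and syllable trains with controlled
   inter-onset variability — every dynamic coupled linearly to severity.
2. **Feature extraction.** Alternation filtering of tap logs, inter-tap
   interval SD per time frame; autocorrelation F0 tracking, glottal-cycle
   extraction, local jitter/shimmer, Stevens-compressed loudness; energy
   onset detection and syllable interval SD. Every task is segmented into
   five equal time frames (TF1–TF5: 4 s tapping, 2 s phonation, 1 s speech).
3. **Statistics.** Pooled-variance group contrasts, within-group
   repeated-measures ANOVA over frames with Holm post hoc tests vs TF1, and
   linear mixed models with a random intercept per subject:

   `value ~ TF + group + TF:group` and, within PD,
   `value ~ TF + UPDRS + TF:UPDRS`

   where TF is numeric 1..5. The `TF:UPDRS` coefficient — the
   *time-severity interaction* — is the headline quantity: it is negative
   for loudness (faster decline at higher severity) and positive for jitter
   and shimmer (faster destabilisation).

## Worked example

```r
library(tapvoice)

res <- run_all(run_config(n_pd = 20, n_control = 20, seed = 7))
subset(as.data.frame(res$report$lmm_time_severity), term == "tf:updrs3",
       select = c(task, feature, estimate, se, p))
```

```
      task              feature  estimate       se        p
4  tapping      tap_variability  0.000229 1.44e-04 1.12e-01
8        a             loudness -0.008383 5.46e-04 7.85e-45
12       a               jitter  0.000104 7.42e-06 9.03e-39
16       a              shimmer  0.003457 2.63e-04 9.55e-35
20       i             loudness -0.004980 4.41e-04 7.50e-27
24       i               jitter  0.000193 7.71e-06 3.18e-94
28       i              shimmer  0.005017 2.80e-04 2.05e-57
32  dadada interval_variability  0.001769 1.58e-03 2.64e-01
36  pataka interval_variability -0.011941 2.76e-03 1.79e-05
```

Each row is a time-by-severity interaction: e.g. `/a/ loudness -0.0084`
means a subject 10 UPDRS-III points more severe loses an extra ~0.08
loudness units per time frame relative to a milder subject — this cohort
was generated with a true slope of −0.0083, and the model recovers it. `res$report` also holds the group-comparison table (PD taps less and
more irregularly, with higher jitter/shimmer and fewer syllable repeats),
the frame-wise ANOVA with the first post hoc frame that departs from TF1,
the severity correlation panel, and a recovery section comparing every
estimate with the generator truth.

The numbered drivers under `analysis/` run the same workflow as a
narrative: `01_simulate_cohort.R` (cohort + raw tap/WAV exports),
`02_extract_features.R` (signal-tier extraction), `03_group_and_time_analysis.R`
(the full statistical battery), `04_recovery_and_calibration.R`
(truth-recovery diagnostics). Outputs land under `results/`.

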