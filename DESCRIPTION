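Package: tapvoice
Title: Time-Frame Analysis of Smartphone Finger-Tapping and Voice Tasks in
    Parkinson Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses short smartphone-based motor and vocal
    assessments for Parkinson disease. Provides a synthetic-cohort generator
    (alternating finger-tap logs, sustained-vowel phonation and rapid-syllable
    audio with known ground truth), self-contained extraction of inter-tap
    interval variability, loudness, local jitter and shimmer, and syllable-onset
    timing per five equal time frames, and the statistical battery for
    group contrasts, time-course ANOVA and linear mixed models with
    time-by-group and time-by-severity interaction terms, including
    simulation-based calibration and parameter-recovery diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    lmerTest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
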