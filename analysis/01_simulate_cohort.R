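#!/usr/bin/env Rscript
# Simulate the study cohort: 20 persons with PD and 20 controls, severity
# sampled around UPDRS part III 22.1 (SD 10.6), with tap logs and audio for
# 2 sessions (2 hands tapping; 3 trials per vocal task). Writes the raw
# data layout a real study export would have: cohort.csv, taps/*.csv,
# audio/*.wav, and the generator ground truth.
#
# Audio for a full cohort is bulky; by default this driver writes raw files
# for the first 2 subjects per group only and keeps the rest in memory for
# the next stage (02 regenerates deterministically from the same seed).

library(tapvoice)

seed <- 7L
out <- "results/cohort_run"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- sample_cohort(n_pd = 20, n_control = 20, scenario = "paper_like",
                        seed = seed)
utils::write.csv(cohort$profiles, file.path(out, "cohort.csv"),
                 row.names = FALSE)
jsonlite::write_json(
  list(scenario = cohort$truth$scenario, seed = cohort$truth$seed,
       betas = cohort$truth$betas, subjects = cohort$truth$subjects),
  file.path(out, "truth.json"), dataframe = "rows", auto_unbox = TRUE,
  digits = NA)

demo_ids <- c(cohort$profiles$subject_id[1:2],
              cohort$profiles$subject_id[21:22])
demo <- cohort
demo$profiles <- demo$profiles[demo$profiles$subject_id %in% demo_ids, ]
invisible(extract_cohort_features(demo, n_sessions = 1, n_trials = 1,
                                  out_dir = out))

cat("cohort:", nrow(cohort$profiles), "subjects;",
    sum(cohort$profiles$group == "PD"), "PD\n")
cat("PD UPDRS III: mean", round(mean(cohort$profiles$updrs3, na.rm = TRUE), 1),
    "SD", round(sd(cohort$profiles$updrs3, na.rm = TRUE), 1), "\n")
cat("raw demo files under", out, "(taps/, audio/)\n")
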