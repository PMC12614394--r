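test_that("cohort sampling respects group sizes, severity fields and bounds", {
  coh <- sample_cohort(20, 20, "paper_like", seed = 7)
  expect_equal(nrow(coh$profiles), 40)
  expect_equal(sum(!is.na(coh$profiles$updrs3)), 20)
  pd <- coh$profiles[coh$profiles$group == "PD", ]
  expect_true(all(pd$updrs3 >= 5 & pd$updrs3 <= 60))
  expect_true(all(pd$hy %in% c(1.5, 2, 2.5, 3)))
  ct <- coh$profiles[coh$profiles$group == "control", ]
  expect_true(all(is.na(ct$updrs3)) && all(is.na(ct$hy)))
  expect_error(sample_cohort(0, 5), "positive")
})

test_that("the null scenario has exactly zero interaction and severity couplings", {
  coh <- sample_cohort(1, 1, "null_interaction", seed = 1)
  expect_true(all(coh$truth$betas$b_int == 0))
  expect_true(all(coh$truth$betas$b_sev == 0))
  expect_true(all(coh$truth$signal_int$d_slope_du == 0))
})

test_that("cohort and trial generation are byte-identical under the same seed", {
  a <- sample_cohort(5, 5, "paper_like", seed = 3)
  b <- sample_cohort(5, 5, "paper_like", seed = 3)
  expect_identical(a, b)
  ta <- simulate_tap_trial(a$profiles[1, ], a$truth, "left", 1)
  tb <- simulate_tap_trial(b$profiles[1, ], b$truth, "left", 1)
  expect_identical(ta, tb)
  wa <- synthesize_phonation(a$profiles[1, ], a$truth, "a", "s1_t1")
  wb <- synthesize_phonation(b$profiles[1, ], b$truth, "a", "s1_t1")
  expect_identical(wa$samples, wb$samples)
  sa <- synthesize_syllable_train(a$profiles[2, ], a$truth, "pataka", "s1_t1")
  sb <- synthesize_syllable_train(b$profiles[2, ], b$truth, "pataka", "s1_t1")
  expect_identical(sa$samples, sb$samples)
})

test_that("tap trials last 20 s and degrade across frames as injected", {
  truth <- tiny_cohort$truth
  prof <- tiny_cohort$profiles[3, ]  # control
  # protocol duration
  trial <- simulate_tap_trial(prof, truth, "right", 1)
  expect_true(all(trial$events$t_sec >= 0 & trial$events$t_sec <= 20))

  # empirical interval SD grows from TF1 to TF5 on average (positive slope)
  sds <- t(sapply(1:60, function(r) {
    tr <- simulate_tap_trial(prof, truth, "right", r, duplicate_frac = 0)
    interval_sd_per_tf(compute_intervals(tr$events))
  }))
  m <- colMeans(sds, na.rm = TRUE)
  expect_gt(m[5], m[1])
})

test_that("zero frame slope and no duplicates give homogeneous frames", {
  coh <- sample_cohort(2, 2, seed = 9)
  coh$truth$subjects$tap_tf_slope <- 0
  prof <- coh$profiles[1, ]
  sds <- t(sapply(1:80, function(r) {
    tr <- simulate_tap_trial(prof, coh$truth, "left", r, duplicate_frac = 0)
    interval_sd_per_tf(compute_intervals(tr$events))
  }))
  m <- colMeans(sds, na.rm = TRUE)
  expect_lt(max(m) / min(m), 1.25)  # statistically equal across frames
})

test_that("higher severity produces higher tapping variability on average", {
  coh <- sample_cohort(2, 1, seed = 5)
  # same subject machinery, two severity levels injected via truth
  truth_lo <- coh$truth; truth_hi <- coh$truth
  truth_lo$subjects$tap_sigma0 <- 0.030 + 0.0032 * 10
  truth_lo$subjects$tap_tf_slope <- 0.002 + 0.00035 * 10
  truth_hi$subjects$tap_sigma0 <- 0.030 + 0.0032 * 40
  truth_hi$subjects$tap_tf_slope <- 0.002 + 0.00035 * 40
  prof <- coh$profiles[1, ]
  sd_of <- function(truth, r) {
    tr <- simulate_tap_trial(prof, truth, "left", r, duplicate_frac = 0)
    stats::sd(compute_intervals(tr$events)$dt)
  }
  lo <- mean(sapply(1:50, function(r) sd_of(truth_lo, r)))
  hi <- mean(sapply(1:50, function(r) sd_of(truth_hi, r + 500)))
  expect_gt(hi, lo)
})

test_that("audio trials have the protocol durations to within one sample", {
  prof <- tiny_cohort$profiles[1, ]
  w <- synthesize_phonation(prof, tiny_cohort$truth, "i", "s1_t1", 8000)
  expect_equal(length(w$samples), 10 * 8000)
  s <- synthesize_syllable_train(prof, tiny_cohort$truth, "dadada", "s1_t1", 8000)
  expect_equal(length(s$samples), 5 * 8000)
  expect_error(synthesize_phonation(prof, tiny_cohort$truth, "a", "x", 4000),
               "8000")
  expect_error(synthesize_syllable_train(prof, tiny_cohort$truth, "pataka",
                                         "x", 4000), "8000")
})

test_that("unperturbed phonation is strictly periodic at sample resolution", {
  prof <- tiny_cohort$profiles[1, ]
  w <- synthesize_phonation(prof, tiny_cohort$truth, "a", "z", snr_db = Inf,
                            overrides = list(jitter0 = 0, jitter_slope = 0,
                                             shimmer0 = 0, shimmer_slope = 0,
                                             amp_slope = 0))
  expect_lt(diff(range(w$truth$period)), 1 / w$rate)
  expect_lt(diff(range(w$truth$amplitude)), 1e-12)
})

test_that("syllable trains honour the nominal rate and severity ordering", {
  prof <- tiny_cohort$profiles[1, ]
  # zero variability -> exactly equally spaced onsets
  s0 <- synthesize_syllable_train(prof, tiny_cohort$truth, "dadada", "x",
                                  overrides = list(ioi_mean = 0.14, ioi_sd0 = 0))
  expect_equal(diff(range(diff(s0$truth$onsets))), 0)
  # ~36 onsets in 5 s at 140 ms nominal spacing
  expect_equal(length(s0$truth$onsets), 36, tolerance = 0.06)

  # true interval SD larger for high severity (by construction, aggregated)
  sd_true <- function(ioi_sd, r) {
    s <- synthesize_syllable_train(prof, tiny_cohort$truth, "pataka",
                                   paste0("r", r),
                                   overrides = list(ioi_sd0 = ioi_sd))
    stats::sd(diff(s$truth$onsets))
  }
  lo <- mean(sapply(1:30, function(r) sd_true(0.008, r)))
  hi <- mean(sapply(1:30, function(r) sd_true(0.021, r + 100)))
  expect_gt(hi, lo)
})

test_that("feature tier reproduces the generating group structure", {
  coh <- sample_cohort(12, 12, seed = 21)
  ft <- simulate_feature_table(coh, include_taps = FALSE)
  # schema: one record per subject x trial x tf x feature
  expect_false(any(duplicated(ft[, c("subject_id", "task", "trial", "tf",
                                     "feature")])))
  # strictly positive features stay positive
  pos <- ft$feature %in% c("jitter", "shimmer", "interval_variability")
  expect_true(all(ft$value[pos] > 0))
  # PD jitter exceeds control jitter at the configured effect size
  g <- group_compare(ft, "jitter", "a")
  expect_lt(g$mean_control, g$mean_pd)
})
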