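test_that("loudness is compressed RMS with the documented scaling law", {
  silent <- list(samples = numeric(8000), rate = 8000)
  expect_true(all(frame_loudness(silent)$loudness == 0))

  tone <- sine_wave(100, dur = 0.5, rate = 16000)
  lo <- frame_loudness(tone)
  # full-scale sine: RMS 0.7071 (intensity 0.5) before compression
  expect_equal(median(lo$loudness), 0.5^0.3, tolerance = 1e-3)
  expect_equal(median(lo$loudness)^(1 / 0.6), 0.7071, tolerance = 1e-3)

  # amplitude 0.2 -> 0.4 multiplies loudness by 2^0.6
  lo1 <- frame_loudness(sine_wave(100, 0.5, 16000, amp = 0.2))
  lo2 <- frame_loudness(sine_wave(100, 0.5, 16000, amp = 0.4))
  expect_equal(median(lo2$loudness) / median(lo1$loudness), 2^0.6,
               tolerance = 1e-6)
  expect_error(frame_loudness(list(samples = numeric(0), rate = 8000)),
               "empty")
})

test_that("autocorrelation pitch tracking recovers pure tones and rejects noise", {
  tone <- sine_wave(200, dur = 2)
  f0 <- estimate_f0(tone)
  expect_true(all(f0$voiced))
  expect_true(all(abs(f0$f0 - 200) <= 2))

  noise <- withr::with_seed(1, list(samples = rnorm(32000, 0, 0.1), rate = 16000))
  f0n <- estimate_f0(noise)
  expect_gt(mean(!f0n$voiced), 0.9)

  silent <- list(samples = numeric(16000), rate = 16000)
  expect_true(all(!estimate_f0(silent)$voiced))

  expect_error(estimate_f0(tone, fmin = 500, fmax = 100), "fmin")
})

test_that("jitter/shimmer implement local relative perturbation", {
  expect_equal(jitter_local(rep(0.005, 50)), 0)
  expect_equal(jitter_local(rep(c(0.009, 0.011), 25)), 0.2)
  expect_true(is.na(jitter_local(0.005)))
  expect_equal(shimmer_local(rep(c(0.9, 1.1), 25)), 0.2)
  expect_equal(shimmer_local(rep(1, 10)), 0)
})

test_that("coefficient of variation is sample SD over mean and scale-free", {
  expect_equal(coefficient_of_variation(c(2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2)
  expect_equal(coefficient_of_variation(c(1, 3)), 0.7071, tolerance = 1e-4)
  v <- c(1.2, 3.4, 2.2, 0.8)
  expect_equal(coefficient_of_variation(v * 17), coefficient_of_variation(v))
  expect_true(is.na(coefficient_of_variation(2)))
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("period extraction marks every frame and partitions cycles disjointly", {
  prof <- tiny_cohort$profiles[1, ]
  w <- synthesize_phonation(prof, tiny_cohort$truth, "a", "pe")
  cyc <- extract_periods(w)
  expect_setequal(unique(cyc$tf), 1:5)
  expect_equal(sum(tabulate(cyc$tf, 5)), nrow(cyc))
  # periods concentrate near the true fundamental period
  expect_equal(median(cyc$period), 1 / w$truth$f0, tolerance = 0.02)
})

test_that("a strictly periodic 200 Hz vowel yields constant periods", {
  prof <- tiny_cohort$profiles[1, ]
  w <- synthesize_phonation(prof, tiny_cohort$truth, "a", "const",
                            snr_db = Inf,
                            overrides = list(f0 = 200, jitter0 = 0,
                                             jitter_slope = 0, shimmer0 = 0,
                                             shimmer_slope = 0, amp_slope = 0))
  cyc <- extract_periods(w)
  expect_equal(median(cyc$period), 0.005, tolerance = 1e-3)
  expect_lt(diff(range(cyc$period)), 1 / w$rate)
  expect_lt(jitter_local(cyc$period), 1e-6)
  expect_lt(shimmer_local(cyc$amplitude), 1e-6)
})

test_that("jitter and shimmer are amplitude-invariant; loudness is not", {
  prof <- tiny_cohort$profiles[2, ]
  w <- synthesize_phonation(prof, tiny_cohort$truth, "i", "sc")
  half <- w; half$samples <- w$samples / 2
  c1 <- extract_periods(w); c2 <- extract_periods(half)
  expect_equal(jitter_local(c2$period), jitter_local(c1$period),
               tolerance = 5e-3)
  expect_equal(shimmer_local(c2$amplitude), shimmer_local(c1$amplitude),
               tolerance = 5e-3)
  l1 <- frame_loudness(w); l2 <- frame_loudness(half)
  expect_equal(median(l2$loudness) / median(l1$loudness), 0.5^0.6,
               tolerance = 1e-2)
})

test_that("onset detection is exact on clean trains and silent on silence", {
  expect_equal(nrow(detect_onsets(list(samples = numeric(40000), rate = 8000))), 0)

  prof <- tiny_cohort$profiles[1, ]
  s <- synthesize_syllable_train(prof, tiny_cohort$truth, "dadada", "od",
                                 overrides = list(ioi_mean = 0.14,
                                                  ioi_sd0 = 0.012))
  det <- detect_onsets(s)
  expect_equal(nrow(det), length(s$truth$onsets))
  expect_true(all(abs(det$onset - s$truth$onsets) <= 0.02))
})

test_that("speech summaries count onsets and spread intervals over frames", {
  tr <- tibble::tibble(onset = seq(0.05, 4.95, by = 0.14))
  out <- speech_summary(tr, task = "dadada")
  expect_equal(out$value[out$feature == "repeat_count"], 36)
  expect_equal(out$value[out$feature == "interval_variability" & out$tf == 0], 0)

  out2 <- speech_summary(tibble::tibble(onset = c(0, 0.2, 0.5)))
  expect_equal(out2$value[out2$feature == "interval_variability" & out2$tf == 0],
               0.0707, tolerance = 1e-3)

  out3 <- speech_summary(tibble::tibble(onset = numeric(0)))
  expect_equal(out3$value[out3$feature == "repeat_count"], 0)
})

test_that("phonation summaries emit 5 frame rows per feature and track drifts", {
  prof <- tiny_cohort$profiles[1, ]
  # stationary trial: per-TF jitter flat, CV small
  w <- synthesize_phonation(prof, tiny_cohort$truth, "a", "st",
                            overrides = list(jitter_slope = 0,
                                             shimmer_slope = 0, amp_slope = 0))
  ps <- phonation_summary(w)
  for (f in c("loudness", "jitter", "shimmer")) {
    expect_equal(sum(ps$feature == f & ps$tf > 0), 5)
  }
  expect_lt(ps$value[ps$feature == "jitter_cv"], 0.15)

  # injected negative loudness drift shows up as a negative per-TF slope
  wd <- synthesize_phonation(prof, tiny_cohort$truth, "a", "dr",
                             overrides = list(amp_slope = -0.02))
  pd <- phonation_summary(wd)
  lo <- pd$value[pd$feature == "loudness" & pd$tf > 0]
  expect_lt(unname(stats::coef(stats::lm(lo ~ seq_along(lo)))[2]), 0)

  # unvoiced input -> missing phonation features
  noise <- withr::with_seed(2, list(samples = rnorm(80000, 0, 0.05),
                                    rate = 8000, task = "a"))
  pn <- phonation_summary(noise)
  expect_true(all(is.na(pn$value[pn$feature %in% c("jitter", "shimmer")])))
})
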