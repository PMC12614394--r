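# Harmonic amplitude weights for a vowel: 1/h source spectrum shaped by two
# fixed resonances (a crude but sufficient formant filter; only the relative
# within-trial dynamics matter downstream).
vowel_weights <- function(vowel, f0, n_harm = 8) {
  formants <- switch(vowel,
    a = c(800, 1200),
    i = c(300, 2300),
    stop("unknown vowel ", vowel, call. = FALSE))
  bw <- 170
  f <- f0 * seq_len(n_harm)
  gain <- function(fc) 1 / sqrt(1 + ((f - fc) / bw)^2)
  w <- (1 / seq_len(n_harm)) * (gain(formants[1]) + 0.6 * gain(formants[2]))
  w / max(w)
}

# One normalized cycle shape evaluated at phases in [0, 1): unit peak.
cycle_shape <- function(phase, weights) {
  x <- 0
  for (h in seq_along(weights)) {
    x <- x + weights[h] * sin(2 * pi * h * phase)
  }
  x
}

add_noise <- function(x, snr_db) {
  if (!is.finite(snr_db)) return(x)
  p_sig <- mean(x^2)
  sigma <- sqrt(p_sig / 10^(snr_db / 10))
  x + rnorm(length(x), 0, sigma)
}

#' Synthesize a sustained-vowel phonation trial
#'
#' Builds a 10 s harmonic waveform cycle by cycle. The base period is
#' snapped to an integer number of samples; each cycle's period is then
#' perturbed multiplicatively so that the expected local jitter (mean
#' absolute consecutive-period difference over mean period) in frame `k`
#' equals `jitter0 + jitter_slope * (k - 1)`, and analogously each cycle's
#' amplitude carries the target local shimmer. The subject's amplitude
#' additionally drifts linearly across frames (`amp_slope`, relative per
#' frame), which is the loudness dynamic. With all perturbations zero and
#' `snr_db = Inf` the output is exactly periodic at sample resolution.
#' Additive white noise is scaled to the requested SNR (default 30 dB).
#'
#' The true per-cycle periods and amplitudes are returned alongside the
#' samples so extraction can be scored against ground truth.
#'
#' @param profile One row of the cohort profiles.
#' @param truth Cohort truth list.
#' @param vowel `"a"` or `"i"`.
#' @param trial Trial label used for the RNG substream (e.g. `"s1_t2"`).
#' @param sample_rate Sampling rate in Hz, at least 8000.
#' @param snr_db Signal-to-noise ratio of the additive noise; `Inf` disables.
#' @param overrides Named list overriding subject truth parameters
#'   (`jitter0`, `jitter_slope`, `shimmer0`, `shimmer_slope`, `amp0`,
#'   `amp_slope`, `f0`); used by the recovery tests to inject known levels.
#' @return A waveform list: `samples` (numeric in \[-1, 1\]), `rate`, `task`,
#'   `duration`, and `truth` (per-cycle `t_end`, `period`, `amplitude`, and
#'   the frame-wise injected jitter/shimmer levels).
#' @export
synthesize_phonation <- function(profile, truth, vowel = c("a", "i"),
                                 trial = "s1_t1", sample_rate = 16000,
                                 snr_db = 30, overrides = list()) {
  vowel <- match.arg(vowel)
  if (sample_rate < 8000) stop("sample_rate must be >= 8000 Hz", call. = FALSE)
  pars <- as.list(truth$subjects[truth$subjects$subject_id == profile$subject_id, ])
  if (length(pars$subject_id) != 1L) {
    stop("unknown subject ", profile$subject_id, call. = FALSE)
  }
  pars[names(overrides)] <- overrides
  duration <- 10
  seed <- derive_seed(truth$seed, profile$subject_id, "phon", vowel, trial)

  with_local_seed(seed, {
    # base period snapped to the sample grid
    n0 <- round(sample_rate / pars$f0)
    t0 <- n0 / sample_rate
    weights <- vowel_weights(vowel, 1 / t0)

    # per-cycle truth: frame-dependent jitter/shimmer levels
    n_cycles <- ceiling(duration / t0) + 8
    ends <- numeric(n_cycles); periods <- numeric(n_cycles)
    jit <- numeric(n_cycles); shim <- numeric(n_cycles)
    amps <- numeric(n_cycles)
    t <- 0; i <- 0
    while (t < duration) {
      i <- i + 1
      k <- min(floor(t / (duration / 5)) + 1, 5)
      j_k <- max(pars$jitter0 + pars$jitter_slope * (k - 1), 0)
      s_k <- max(pars$shimmer0 + pars$shimmer_slope * (k - 1), 0)
      # local jitter = 2*sd/sqrt(pi) for i.i.d. normal perturbations
      periods[i] <- t0 * (1 + rnorm(1, 0, j_k * sqrt(pi) / 2))
      amps[i] <- pars$amp0 * (1 + pars$amp_slope * (k - 1)) *
        (1 + rnorm(1, 0, s_k * sqrt(pi) / 2))
      jit[i] <- j_k; shim[i] <- s_k
      t <- t + periods[i]
      ends[i] <- t
    }
    n_cyc <- i
    ends <- ends[1:n_cyc]; periods <- periods[1:n_cyc]
    amps <- pmax(amps[1:n_cyc], 0.01)
    starts <- ends - periods

    n_samp <- round(duration * sample_rate)
    ts <- (seq_len(n_samp) - 1) / sample_rate
    cyc <- findInterval(ts, c(starts[1], ends), rightmost.closed = FALSE)
    cyc[cyc < 1] <- 1; cyc[cyc > n_cyc] <- n_cyc
    phase <- (ts - starts[cyc]) / periods[cyc]
    # unit-peak cycle shape, and the phase where its peak sits
    grid <- seq(0, 1, length.out = 2048)
    shape_grid <- cycle_shape(grid, weights)
    peak_gain <- max(abs(shape_grid))
    phi_star <- grid[which.max(shape_grid)]
    # per-cycle amplitude applied as a piecewise-linear envelope anchored at
    # each cycle's waveform peak, so the peak of cycle i reads exactly A_i
    # and no amplitude step falls inside a cycle
    env <- stats::approx(starts + phi_star * periods, amps, xout = ts,
                         rule = 2)$y
    x <- env * cycle_shape(phase %% 1, weights) / peak_gain
    x <- add_noise(x, snr_db)
    x <- pmin(pmax(x, -1), 1)

    list(
      samples = x, rate = sample_rate, task = vowel, duration = duration,
      truth = list(t_end = ends, period = periods, amplitude = amps,
                   jitter_level = jit[1:n_cyc], shimmer_level = shim[1:n_cyc],
                   amp0 = pars$amp0, amp_slope = pars$amp_slope,
                   f0 = 1 / t0)
    )
  })
}

#' Synthesize a syllable-repetition (diadochokinesis) trial
#'
#' A 5 s train of enveloped voiced bursts (default 120 ms long) whose
#' inter-onset intervals are normal with subject mean `ioi_mean` and SD
#' `ioi_sd0` (truncated so bursts never overlap); in the paper-like
#' scenario both the mean (fewer repeats) and the SD (more irregular
#' timing) increase with UPDRS part III. Gaps between bursts are near
#' silence; white noise is added at the requested SNR (default 20 dB).
#' True onset times are returned for detector scoring.
#'
#' @inheritParams synthesize_phonation
#' @param task `"dadada"` or `"pataka"`.
#' @param burst_dur Burst duration in seconds.
#' @param overrides Named list overriding `ioi_mean`, `ioi_sd0`, `f0`.
#' @return A waveform list with `samples`, `rate`, `task`, `duration`, and
#'   `truth` (`onsets`: true onset times in seconds).
#' @export
synthesize_syllable_train <- function(profile, truth,
                                      task = c("dadada", "pataka"),
                                      trial = "s1_t1", sample_rate = 16000,
                                      snr_db = 20, burst_dur = 0.12,
                                      overrides = list()) {
  task <- match.arg(task)
  if (sample_rate < 8000) stop("sample_rate must be >= 8000 Hz", call. = FALSE)
  pars <- as.list(truth$subjects[truth$subjects$subject_id == profile$subject_id, ])
  if (length(pars$subject_id) != 1L) {
    stop("unknown subject ", profile$subject_id, call. = FALSE)
  }
  pars[names(overrides)] <- overrides
  duration <- 5
  seed <- derive_seed(truth$seed, profile$subject_id, task, trial)

  with_local_seed(seed, {
    # onset times: first onset shortly after trial start, then normal IOIs
    # truncated so consecutive bursts cannot overlap
    onsets <- 0.05
    repeat {
      ioi <- max(rnorm(1, pars$ioi_mean, pars$ioi_sd0), burst_dur + 0.01)
      nxt <- onsets[length(onsets)] + ioi
      if (nxt + burst_dur > duration) break
      onsets <- c(onsets, nxt)
    }

    n_samp <- round(duration * sample_rate)
    x <- numeric(n_samp)
    nb <- round(burst_dur * sample_rate)
    tb <- (seq_len(nb) - 1) / sample_rate
    f0 <- 140
    # sharp attack (8 ms), exponential decay tail: energy onsets are crisp
    env <- pmin(tb / 0.008, 1) * exp(-pmax(tb - (burst_dur - 0.04), 0) / 0.015)
    carrier <- 0.6 * sin(2 * pi * f0 * tb) + 0.3 * sin(2 * pi * 2 * f0 * tb) +
      0.15 * sin(2 * pi * 3 * f0 * tb)
    burst0 <- env * carrier / max(abs(carrier))
    for (on in onsets) {
      i0 <- round(on * sample_rate) + 1
      idx <- i0:min(i0 + nb - 1, n_samp)
      amp <- 0.35 * (1 + rnorm(1, 0, 0.02))
      x[idx] <- x[idx] + amp * burst0[seq_along(idx)]
    }
    x <- add_noise(x, snr_db)
    x <- pmin(pmax(x, -1), 1)
    list(samples = x, rate = sample_rate, task = task, duration = duration,
         truth = list(onsets = onsets))
  })
}
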