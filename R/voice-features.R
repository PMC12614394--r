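# Frame a signal into a (win_samples x n_frames) matrix, centers every `hop`.
frame_signal <- function(x, rate, win, hop) {
  wl <- max(round(win * rate), 2L)
  hl <- max(round(hop * rate), 1L)
  starts <- seq(1L, length(x) - wl + 1L, by = hl)
  idx <- outer(0:(wl - 1L), starts, "+")
  list(mat = matrix(x[idx], nrow = wl),
       centers = (starts - 1L + (wl - 1L) / 2) / rate)
}

#' Frame-wise loudness proxy
#'
#' Short-time intensity (mean squared amplitude per frame) raised to the
#' power 0.3, the Stevens-law compression of intensity into perceived
#' loudness. Equivalently the frame RMS raised to 0.6: doubling the
#' waveform amplitude multiplies the value by `2^0.6`.
#'
#' @param w Waveform list (`samples`, `rate`).
#' @param win,hop Analysis window and hop in seconds (25 ms / 10 ms).
#' @return Tibble with `frame_time` (window centers, s) and `loudness`.
#' @export
frame_loudness <- function(w, win = 0.025, hop = 0.010) {
  if (length(w$samples) == 0) stop("empty waveform", call. = FALSE)
  fr <- frame_signal(w$samples, w$rate, win, hop)
  intensity <- colMeans(fr$mat^2)
  tibble::tibble(frame_time = fr$centers, loudness = intensity^0.3)
}

#' Frame-wise fundamental-frequency track
#'
#' Autocorrelation pitch tracking: per 40 ms frame the normalized
#' autocorrelation (computed via FFT) is maximized over the lag range
#' `[1/fmax, 1/fmin]`; frames whose peak falls below `voicing_threshold`
#' (or whose energy is negligible) are marked unvoiced. The peak lag is
#' refined by parabolic interpolation.
#'
#' @param w Waveform list (`samples`, `rate`, rate >= 8 kHz).
#' @param fmin,fmax F0 search bounds in Hz.
#' @param win,hop Window / hop in seconds.
#' @param voicing_threshold Normalized-autocorrelation voicing cutoff.
#' @return Tibble with `frame_time`, `f0` (Hz, `NA` when unvoiced),
#'   `voiced`, and `rho` (peak normalized autocorrelation).
#' @export
estimate_f0 <- function(w, fmin = 75, fmax = 500, win = 0.040, hop = 0.010,
                        voicing_threshold = 0.45) {
  if (fmin >= fmax) stop("fmin must be below fmax", call. = FALSE)
  if (w$rate < 8000) stop("sample rate must be >= 8000 Hz", call. = FALSE)
  fr <- frame_signal(w$samples, w$rate, win, hop)
  wl <- nrow(fr$mat)
  nfft <- stats::nextn(2L * wl, c(2, 3, 5))
  padded <- rbind(fr$mat, matrix(0, nfft - wl, ncol(fr$mat)))
  spec <- stats::mvfft(padded)
  ac <- Re(stats::mvfft(Mod(spec)^2 * (1 + 0i), inverse = TRUE)) / nfft

  lag_min <- max(floor(w$rate / fmax), 2L)
  lag_max <- min(ceiling(w$rate / fmin), wl - 2L)
  lags <- lag_min:lag_max
  r0 <- ac[1L, ]
  energy_floor <- 1e-6 * max(r0)
  seg <- t(ac[lags + 1L, , drop = FALSE])    # frames x lags
  n_frames <- nrow(seg)
  best <- max.col(seg, ties.method = "first")
  ok <- r0 > energy_floor
  rho <- ifelse(ok, seg[cbind(seq_len(n_frames), best)] / r0, 0)
  lag <- lags[best]
  # parabolic refinement of the autocorrelation peak
  inner <- best > 1L & best < length(lags)
  i <- which(inner)
  if (length(i)) {
    y1 <- seg[cbind(i, best[i] - 1L)]
    y2 <- seg[cbind(i, best[i])]
    y3 <- seg[cbind(i, best[i] + 1L)]
    denom <- y1 - 2 * y2 + y3
    lag[i] <- lag[i] + ifelse(denom < 0, 0.5 * (y1 - y3) / denom, 0)
  }
  f0 <- w$rate / lag
  voiced <- ok & rho >= voicing_threshold
  f0[!voiced] <- NA_real_
  tibble::tibble(frame_time = fr$centers, f0 = f0, voiced = voiced, rho = rho)
}

#' Glottal-cycle analog extraction
#'
#' Marks one waveform peak per fundamental period within the voiced part of
#' the recording, refines each mark to sub-sample precision by
#' cross-correlating the local segment against the trial's average cycle
#' shape, and returns the resulting period and cycle-amplitude sequences.
#' Cycle amplitude is `sqrt(2)` times the RMS over one period centered on
#' the mark (robust to additive noise at the SNRs simulated here). Each
#' period is assigned to the time frame containing its end mark.
#'
#' @param w Waveform list.
#' @param f0series Output of [estimate_f0()] for the same waveform.
#' @param spec Frame specification (defaults to phonation frames).
#' @return Tibble with `t_end` (s), `period` (s), `amplitude`, `tf`; zero
#'   rows when no voiced frames exist.
#' @export
extract_periods <- function(w, f0series = estimate_f0(w),
                            spec = time_frames("phonation")) {
  x <- w$samples
  rate <- w$rate
  f0v <- f0series$f0[f0series$voiced]
  empty <- tibble::tibble(t_end = numeric(0), period = numeric(0),
                          amplitude = numeric(0), tf = integer(0))
  if (length(f0v) < 3L) return(empty)
  t_hat <- rate / stats::median(f0v)          # period in samples

  # peak picking: one mark per period, greedy forward march
  n <- length(x)
  marks <- integer(0)
  m <- which.max(x[1:min(n, ceiling(1.5 * t_hat))])
  while (m + 0.5 * t_hat < n) {
    marks <- c(marks, m)
    lo <- m + floor(0.5 * t_hat)
    hi <- min(m + ceiling(1.5 * t_hat), n)
    if (lo >= hi) break
    m <- lo - 1L + which.max(x[lo:hi])
    if (m <= marks[length(marks)]) break
  }
  if (length(marks) < 4L) return(empty)

  # sub-sample refinement against the average cycle shape
  hw <- max(floor(t_hat / 3), 4L)
  usable <- marks > hw + 3L & marks <= n - hw - 3L
  marks <- marks[usable]
  if (length(marks) < 4L) return(empty)
  seg_idx <- outer(-hw:hw, marks, "+")
  template <- rowMeans(matrix(x[seg_idx], nrow = 2L * hw + 1L))
  offs <- -3:3
  scores <- vapply(offs, function(o) {
    colSums(matrix(x[seg_idx + o], nrow = 2L * hw + 1L) * template)
  }, numeric(length(marks)))
  bi <- max.col(scores)
  shift <- offs[bi]
  inner <- bi > 1L & bi < length(offs)
  refined <- marks + shift
  if (any(inner)) {
    i <- which(inner)
    y1 <- scores[cbind(i, bi[i] - 1L)]
    y2 <- scores[cbind(i, bi[i])]
    y3 <- scores[cbind(i, bi[i] + 1L)]
    denom <- y1 - 2 * y2 + y3
    adj <- ifelse(denom < 0, 0.5 * (y1 - y3) / denom, 0)
    refined[i] <- refined[i] + adj
  }

  # cycle amplitudes: peak of the lightly smoothed waveform at the mark
  # (a 5-sample moving average suppresses the additive noise; the constant
  # peak attenuation it causes cancels in the relative shimmer)
  xs <- stats::filter(x, rep(0.2, 5L), sides = 2)
  aidx <- outer(-3:3, marks, "+")
  amp <- apply(matrix(abs(xs[aidx]), nrow = 7L), 2L, max)

  t_marks <- (refined - 1) / rate
  keep_t <- t_marks >= 0 & t_marks <= attr(spec, "duration")
  periods <- diff(t_marks)
  res <- tibble::tibble(
    t_end = t_marks[-1L],
    period = periods,
    amplitude = amp[-1L],
    tf = NA_integer_
  )
  res <- res[res$t_end >= 0 & res$t_end <= attr(spec, "duration") &
               res$period > 0, ]
  res$tf <- assign_time_frame(res$t_end, spec)
  res
}

# mean absolute consecutive difference over the mean: the shared "local
# relative perturbation" formula behind jitter and shimmer
local_perturbation <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) < 2L) return(NA_real_)
  mean(abs(diff(v))) / mean(v)
}

#' Local jitter
#'
#' Mean absolute difference between consecutive fundamental periods divided
#' by the mean period (dimensionless, the local relative jitter convention).
#'
#' @param periods Numeric vector of periods in seconds, or a period table
#'   from [extract_periods()].
#' @return Dimensionless ratio; `NA` with fewer than two periods.
#' @examples
#' jitter_local(rep(c(0.009, 0.011), 10)) # 0.2
#' @export
jitter_local <- function(periods) {
  if (is.data.frame(periods)) periods <- periods$period
  local_perturbation(periods)
}

#' Local shimmer
#'
#' As [jitter_local()], applied to per-cycle peak amplitudes.
#'
#' @param amplitudes Numeric vector of cycle amplitudes, or a period table
#'   from [extract_periods()].
#' @return Dimensionless ratio; `NA` with fewer than two cycles.
#' @export
shimmer_local <- function(amplitudes) {
  if (is.data.frame(amplitudes)) amplitudes <- amplitudes$amplitude
  local_perturbation(amplitudes)
}

#' Detect syllable onsets from the energy envelope
#'
#' The squared signal is smoothed with a centered moving-average window
#' (default 20 ms); onsets are upward crossings of
#' `threshold_rel * (95th percentile of the envelope)`, with crossings
#' closer than `min_gap` to the previous accepted onset suppressed.
#'
#' @param w Waveform list.
#' @param min_gap Minimum onset spacing in seconds.
#' @param threshold_rel Threshold as a fraction of the envelope's 95th
#'   percentile.
#' @param win Envelope smoothing window in seconds.
#' @return Tibble with a single column `onset` (seconds, strictly
#'   increasing); zero rows for silence.
#' @export
detect_onsets <- function(w, min_gap = 0.08, threshold_rel = 0.2,
                          win = 0.020) {
  x <- w$samples
  wl <- max(round(win * w$rate), 3L)
  if (wl %% 2L == 0L) wl <- wl + 1L
  env <- sqrt(pmax(stats::filter(x^2, rep(1 / wl, wl), sides = 2), 0))
  env[is.na(env)] <- 0
  ref <- stats::quantile(env, 0.95, names = FALSE)
  if (ref <= 0) return(tibble::tibble(onset = numeric(0)))
  thr <- threshold_rel * ref
  above <- env > thr
  rises <- which(above & !c(FALSE, above[-length(above)]))
  if (length(rises) == 0) return(tibble::tibble(onset = numeric(0)))
  # a crossing only counts as an onset if the envelope climbs well past the
  # threshold right after it (true attacks do within ~10 ms; ripple on a
  # decaying tail does not), and respects the minimum onset spacing
  confirm <- round(0.012 * w$rate)
  n <- length(env)
  confirmed <- vapply(rises, function(r) {
    max(env[r:min(r + confirm, n)]) > 2.5 * thr
  }, logical(1))
  rises <- rises[confirmed]
  if (length(rises) == 0) return(tibble::tibble(onset = numeric(0)))
  kept <- rises[1]
  for (r in rises[-1]) {
    if ((r - kept[length(kept)]) / w$rate >= min_gap) kept <- c(kept, r)
  }
  tibble::tibble(onset = (kept - 1) / w$rate)
}

#' Summarise a syllable-repetition trial
#'
#' Repeat count (number of detected onsets), the overall sample SD of the
#' intervals between consecutive onsets, and the per-time-frame interval SD
#' (an interval belongs to the frame containing its later onset).
#'
#' @param train Onset table from [detect_onsets()] (column `onset`).
#' @param spec Frame specification (defaults to the 1 s speech frames).
#' @param task Task label stored in the records.
#' @return Long tibble of feature records (`task`, `tf`, `feature`,
#'   `value`); `tf = 0` rows hold the whole-trial features.
#' @export
speech_summary <- function(train, spec = time_frames("speech"),
                           task = "dadada") {
  onsets <- train$onset
  n <- length(onsets)
  if (n < 2L) {
    return(tibble::tibble(task = task, tf = 0L, feature = "repeat_count",
                          value = as.numeric(n)))
  }
  dt <- diff(onsets)
  t_end <- onsets[-1L]
  tf <- assign_time_frame(pmin(t_end, attr(spec, "duration")), spec)
  per_tf <- vapply(1:5, function(k) {
    v <- dt[tf == k]
    if (length(v) >= 2L) stats::sd(v) else NA_real_
  }, numeric(1))
  tibble::tibble(
    task = task,
    tf = c(0L, 0L, 1:5),
    feature = c("repeat_count", "interval_variability",
                rep("interval_variability", 5)),
    value = c(n, stats::sd(dt), per_tf)
  )
}

#' Summarise a sustained-phonation trial
#'
#' Per-time-frame loudness (mean of frame loudness over the frames whose
#' centers fall in the TF), local jitter and shimmer from the TF's cycle
#' sequence, plus whole-trial aggregates: the mean of the five per-TF
#' values and the jitter/shimmer variability (coefficient of variation of
#' the five per-TF values).
#'
#' @param w Waveform list (task `"a"` or `"i"`).
#' @param spec Frame specification (defaults to the 2 s phonation frames).
#' @param task Task label; defaults to `w$task`.
#' @return Long tibble of feature records; all values `NA` when the trial
#'   has no voiced content.
#' @export
phonation_summary <- function(w, spec = time_frames("phonation"),
                              task = w$task) {
  lo <- frame_loudness(w)
  f0s <- estimate_f0(w)
  cyc <- extract_periods(w, f0s, spec)
  tf_lo <- assign_time_frame(pmin(lo$frame_time, attr(spec, "duration")), spec)
  loud <- vapply(1:5, function(k) mean(lo$loudness[tf_lo == k]), numeric(1))
  if (nrow(cyc) == 0L) {
    jit <- rep(NA_real_, 5); shi <- rep(NA_real_, 5)
    loud <- rep(NA_real_, 5)
  } else {
    jit <- vapply(1:5, function(k) jitter_local(cyc$period[cyc$tf == k]),
                  numeric(1))
    shi <- vapply(1:5, function(k) shimmer_local(cyc$amplitude[cyc$tf == k]),
                  numeric(1))
  }
  cv_or_na <- function(v) {
    if (sum(!is.na(v)) < 2L) NA_real_ else coefficient_of_variation(v, na.rm = TRUE)
  }
  tibble::tibble(
    task = task,
    tf = c(rep(c(0L, 1:5), 3L), 0L, 0L),
    feature = c(rep("loudness", 6), rep("jitter", 6), rep("shimmer", 6),
                "jitter_cv", "shimmer_cv"),
    value = c(mean(loud, na.rm = TRUE), loud,
              mean(jit, na.rm = TRUE), jit,
              mean(shi, na.rm = TRUE), shi,
              cv_or_na(jit), cv_or_na(shi))
  )
}
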