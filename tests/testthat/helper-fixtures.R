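# Shared small fixtures, built once per test run.

# a 2 + 2 cohort for signal-tier spot checks
tiny_cohort <- sample_cohort(2, 2, seed = 42)

# independent brute-force reference for the alternation filter: a plain
# scan keeping the first event and every event whose side differs from the
# last kept side
brute_force_alternation <- function(events) {
  keep <- integer(0)
  last <- NULL
  for (i in seq_len(nrow(events))) {
    if (is.null(last) || events$side[i] != last) {
      keep <- c(keep, i)
      last <- events$side[i]
    }
  }
  events[keep, , drop = FALSE]
}

random_tap_log <- function(n, p_same = 0.3) {
  tibble::tibble(
    t_sec = sort(stats::runif(n, 0, 20)),
    side = character(n)
  ) -> ev
  side <- sample(c("left", "right"), 1)
  for (i in seq_len(n)) {
    if (i > 1 && stats::runif(1) > p_same) {
      side <- setdiff(c("left", "right"), side)
    }
    ev$side[i] <- side
  }
  ev
}

# pure tone waveform helper
sine_wave <- function(freq, dur = 1, rate = 16000, amp = 1) {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  list(samples = amp * sin(2 * pi * freq * t), rate = rate, task = "a",
       duration = dur)
}
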