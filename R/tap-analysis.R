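#' Keep only alternating taps
#'
#' The tapping task asks for strict left/right alternation with two fingers;
#' repeated presses of the same button are excluded from analysis. A tap is
#' retained when its side differs from the side of the previously *retained*
#' tap; the first tap is always retained. Timestamps are untouched, so an
#' excluded tap simply bridges its neighbours into one longer interval.
#'
#' @param events A data frame of tap events with columns `t_sec` (seconds,
#'   sorted non-decreasing) and `side` (`"left"`/`"right"` or any two-level
#'   coding).
#' @return The retained subset of `events`, same columns, original order.
#' @examples
#' ev <- tibble::tibble(t_sec = c(0, .2, .4, .5, .7),
#'                      side = c("L", "R", "L", "L", "R"))
#' filter_alternating(ev)
#' @export
filter_alternating <- function(events) {
  stopifnot(is.data.frame(events), all(c("t_sec", "side") %in% names(events)))
  n <- nrow(events)
  if (n == 0L) return(events)
  if (is.unsorted(events$t_sec)) {
    stop("tap events must be sorted by time", call. = FALSE)
  }
  side <- as.character(events$side)
  keep <- logical(n)
  keep[1L] <- TRUE
  last <- side[1L]
  for (i in seq_len(n)[-1L]) {
    if (side[i] != last) {
      keep[i] <- TRUE
      last <- side[i]
    }
  }
  events[keep, , drop = FALSE]
}

#' Intervals between consecutive taps
#'
#' Each interval is stamped with the time of its *later* tap, which is the
#' timestamp used to place the interval in a time frame.
#'
#' @param events Alternation-filtered tap events (`t_sec`, `side`).
#' @return A tibble with columns `t_end` and `dt` (both seconds); zero rows
#'   when fewer than two taps remain.
#' @export
compute_intervals <- function(events) {
  t <- events$t_sec
  if (length(t) < 2L) {
    return(tibble::tibble(t_end = numeric(0), dt = numeric(0)))
  }
  tibble::tibble(t_end = t[-1L], dt = diff(t))
}

#' Per-time-frame interval variability
#'
#' Sample standard deviation (n - 1 denominator) of the inter-tap intervals
#' falling in each frame; an interval belongs to the frame containing its
#' later tap. Frames holding fewer than two intervals yield `NA`.
#'
#' @param intervals Output of [compute_intervals()].
#' @param spec Frame specification from [time_frames()].
#' @return Named numeric vector of length 5 (`tf1`..`tf5`), SD in seconds.
#' @export
interval_sd_per_tf <- function(intervals, spec = time_frames("tapping")) {
  out <- rep(NA_real_, 5)
  names(out) <- paste0("tf", 1:5)
  if (nrow(intervals) == 0L) return(out)
  tf <- assign_time_frame(intervals$t_end, spec)
  for (k in 1:5) {
    dts <- intervals$dt[tf == k]
    if (length(dts) >= 2L) out[k] <- stats::sd(dts)
  }
  out
}

#' Summarise one tapping trial
#'
#' Applies the alternation filter, computes inter-tap intervals, and returns
#' the trial's feature set in long format: total retained taps, per-frame
#' interval SDs, and their mean (`mean_variability`, the average of the five
#' per-frame SDs).
#'
#' @param trial A tap trial as returned by [simulate_tap_trial()] or
#'   [read_tap_log()]: a list with `subject_id`, `hand`, `session` and an
#'   `events` data frame.
#' @param spec Frame specification; defaults to the tapping frames.
#' @param bridge_excluded With the default `TRUE`, an excluded same-side tap
#'   bridges its neighbours into one longer interval (gap-free series); with
#'   `FALSE`, intervals that span an excluded tap are dropped instead.
#' @return A tibble of feature records with columns `subject_id`, `task`,
#'   `trial`, `tf` (0 for whole-trial features), `feature`, `value`.
#' @export
tap_summary <- function(trial, spec = time_frames("tapping"),
                        bridge_excluded = TRUE) {
  filtered <- filter_alternating(trial$events)
  intervals <- compute_intervals(filtered)
  if (!bridge_excluded && nrow(intervals) > 0) {
    excluded_t <- setdiff(trial$events$t_sec, filtered$t_sec)
    if (length(excluded_t) > 0) {
      t_start <- intervals$t_end - intervals$dt
      spans <- vapply(seq_len(nrow(intervals)), function(i) {
        any(excluded_t > t_start[i] & excluded_t < intervals$t_end[i])
      }, logical(1))
      intervals <- intervals[!spans, ]
    }
  }
  sds <- interval_sd_per_tf(intervals, spec)
  trial_id <- paste0(trial$hand, "_s", trial$session)
  tibble::tibble(
    subject_id = trial$subject_id,
    task = "tapping",
    trial = trial_id,
    tf = c(0L, 0L, 1:5),
    feature = c("total_taps", "tap_variability", rep("tap_variability", 5)),
    value = c(nrow(filtered), mean(sds, na.rm = TRUE), unname(sds))
  )
}

#' Read a tap log written by the simulator
#'
#' Tap logs are two-column CSVs (`t_sec,side`); hand and session are encoded
#' in the filename as `<subject>_<hand>_<session>.csv`.
#'
#' @param path Path to the CSV file.
#' @return A tap-trial list (`subject_id`, `hand`, `session`, `duration`,
#'   `events`).
#' @export
read_tap_log <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  parts <- strsplit(sub("\\.csv$", "", basename(path)), "_")[[1]]
  n <- length(parts)
  list(
    subject_id = paste(parts[seq_len(n - 2L)], collapse = "_"),
    hand = parts[n - 1L],
    session = as.integer(sub("^s", "", parts[n])),
    duration = 20,
    events = tibble::as_tibble(ev)
  )
}
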