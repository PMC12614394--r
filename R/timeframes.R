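#' Time-frame specification for a task
#'
#' Every task recording is split into five equal, contiguous time frames
#' (TFs): 4 s frames for the 20 s tapping task, 2 s frames for 10 s
#' sustained phonation, and 1 s frames for the 5 s syllable-repetition
#' tasks. Frames are half-open `[start, end)` so that every instant of the
#' recording belongs to exactly one frame; the trial-end instant is folded
#' into TF5.
#'
#' @param task_kind One of `"tapping"`, `"phonation"`, `"speech"`.
#' @return A tibble with columns `tf` (1..5), `start`, `end` (seconds), and
#'   attributes `task_kind` and `duration`.
#' @examples
#' time_frames("tapping")
#' @export
time_frames <- function(task_kind = c("tapping", "phonation", "speech")) {
  task_kind <- match.arg(task_kind)
  duration <- switch(task_kind, tapping = 20, phonation = 10, speech = 5)
  width <- duration / 5
  spec <- tibble::tibble(
    tf = 1:5,
    start = width * (0:4),
    end = width * (1:5)
  )
  attr(spec, "task_kind") <- task_kind
  attr(spec, "duration") <- duration
  spec
}

#' Assign timestamps to time frames
#'
#' Half-open assignment: a time `t` belongs to frame `k` when
#' `start_k <= t < end_k`. The exact trial-end instant (`t == duration`)
#' maps to frame 5 so that the partition covers the closed interval.
#'
#' @param t Numeric vector of times in seconds from trial start.
#' @param spec A frame specification from [time_frames()].
#' @return Integer vector of frame indices in 1..5.
#' @examples
#' assign_time_frame(c(0, 4, 19.99, 20), time_frames("tapping"))
#' @export
assign_time_frame <- function(t, spec) {
  duration <- attr(spec, "duration")
  if (any(t < 0 | t > duration)) {
    stop("times must lie within [0, ", duration, "] s", call. = FALSE)
  }
  width <- duration / 5
  tf <- pmin(floor(t / width) + 1L, 5L)
  as.integer(tf)
}
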