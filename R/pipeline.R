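#' Default run configuration
#'
#' All tunables of a full simulate-extract-analyze run in one list. The
#' protocol constants (five time frames; 20 s tapping, 10 s phonation, 5 s
#' speech) are fixed by the task design and not configurable here.
#'
#' @param n_pd,n_control Cohort sizes.
#' @param scenario `"paper_like"` or `"null_interaction"`.
#' @param seed Master seed.
#' @param tier `"feature"` draws feature values directly from the linear
#'   generating model (fast; used for calibration studies); `"signal"`
#'   synthesizes tap logs and audio and runs the full extraction chain.
#' @param n_sessions,n_trials Repetitions per subject (protocol: 2 sessions;
#'   3 trials per vocal task and session).
#' @param sample_rate Audio sampling rate (signal tier).
#' @param alpha,adjust Significance level and multiple-testing adjustment
#'   passed to [build_report()].
#' @param out_dir Optional directory; when set, features, report tables and
#'   simulated raw data are written there.
#' @param write_raw Write tap CSVs / WAV audio under `out_dir` (signal tier).
#' @return A named list (class `tv_config`).
#' @export
run_config <- function(n_pd = 20, n_control = 20, scenario = "paper_like",
                       seed = 1L, tier = c("feature", "signal"),
                       n_sessions = 2, n_trials = 3, sample_rate = 16000,
                       alpha = 0.05, adjust = "none", out_dir = NULL,
                       write_raw = FALSE) {
  structure(list(
    n_pd = n_pd, n_control = n_control, scenario = scenario,
    seed = as.integer(seed), tier = match.arg(tier),
    n_sessions = n_sessions, n_trials = n_trials,
    sample_rate = sample_rate, alpha = alpha, adjust = adjust,
    out_dir = out_dir, write_raw = write_raw
  ), class = "tv_config")
}

config_hash <- function(config) {
  sprintf("%08x", fnv32(paste(deparse(config[order(names(config))]),
                              collapse = "")))
}

#' Extract all features from a simulated cohort through the signal tier
#'
#' Simulates tap logs and audio for every subject, session and trial and
#' runs them through the extraction chain ([tap_summary()],
#' [phonation_summary()], [speech_summary()]).
#'
#' @param cohort A `tv_cohort`.
#' @param n_sessions,n_trials Repetitions (see [run_config()]).
#' @param sample_rate Audio sampling rate in Hz.
#' @param out_dir Optional directory to also write raw tap CSVs and WAVs.
#' @return Long feature table.
#' @export
extract_cohort_features <- function(cohort, n_sessions = 2, n_trials = 3,
                                    sample_rate = 16000, out_dir = NULL) {
  profiles <- cohort$profiles
  truth <- cohort$truth
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "taps"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "audio"), recursive = TRUE, showWarnings = FALSE)
  }
  rows <- vector("list", nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    prof <- profiles[i, ]
    per <- list()
    for (s in seq_len(n_sessions)) {
      for (hand in c("left", "right")) {
        trial <- simulate_tap_trial(prof, truth, hand, s)
        if (!is.null(out_dir)) {
          utils::write.csv(
            trial$events[, c("t_sec", "side")],
            file.path(out_dir, "taps",
                      sprintf("%s_%s_s%d.csv", prof$subject_id, hand, s)),
            row.names = FALSE)
        }
        per[[length(per) + 1L]] <- tap_summary(trial)
      }
      for (r in seq_len(n_trials)) {
        tr <- sprintf("s%d_t%d", s, r)
        for (v in c("a", "i")) {
          w <- synthesize_phonation(prof, truth, v, tr, sample_rate)
          if (!is.null(out_dir)) {
            write_wav(w$samples, w$rate,
                      file.path(out_dir, "audio",
                                sprintf("%s_%s_%s.wav", prof$subject_id, v, tr)))
          }
          ft <- phonation_summary(w)
          ft$subject_id <- prof$subject_id
          ft$trial <- tr
          per[[length(per) + 1L]] <- ft
        }
        for (tk in c("dadada", "pataka")) {
          w <- synthesize_syllable_train(prof, truth, tk, tr, sample_rate)
          if (!is.null(out_dir)) {
            write_wav(w$samples, w$rate,
                      file.path(out_dir, "audio",
                                sprintf("%s_%s_%s.wav", prof$subject_id, tk, tr)))
          }
          ft <- speech_summary(detect_onsets(w), task = tk)
          ft$subject_id <- prof$subject_id
          ft$trial <- tr
          per[[length(per) + 1L]] <- ft
        }
      }
    }
    rows[[i]] <- dplyr::bind_rows(per) |>
      dplyr::mutate(group = prof$group, updrs3 = prof$updrs3)
  }
  out <- dplyr::bind_rows(rows)[, c("subject_id", "group", "updrs3", "task",
                                    "trial", "tf", "feature", "value")]
  attr(out, "tier") <- "signal"
  out
}

#' Run the whole pipeline: simulate, extract, analyze, report
#'
#' One reproducible end-to-end run. The same seed always yields the same
#' cohort, the same feature table and the same report; every written
#' artifact is stamped with the configuration hash and seed.
#'
#' @param config A list from [run_config()].
#' @return List with `cohort`, `features`, `report`, `config`, and `hash`.
#' @examples
#' \donttest{
#' res <- run_all(run_config(n_pd = 4, n_control = 4, seed = 7))
#' res$report$group_comparison
#' }
#' @export
run_all <- function(config = run_config()) {
  cohort <- sample_cohort(config$n_pd, config$n_control, config$scenario,
                          config$seed)
  features <- if (config$tier == "signal") {
    extract_cohort_features(cohort, config$n_sessions, config$n_trials,
                            config$sample_rate,
                            out_dir = if (isTRUE(config$write_raw)) config$out_dir)
  } else {
    simulate_feature_table(cohort, config$n_sessions, config$n_trials)
  }
  report <- build_report(features, cohort, alpha = config$alpha,
                         adjust = config$adjust)
  hash <- config_hash(config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cohort$profiles, file.path(config$out_dir, "cohort.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(scenario = cohort$truth$scenario, seed = cohort$truth$seed,
           config_hash = hash, betas = cohort$truth$betas,
           subjects = cohort$truth$subjects),
      file.path(config$out_dir, "truth.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
    utils::write.csv(cbind(features, config_hash = hash),
                     file.path(config$out_dir, "features.csv"),
                     row.names = FALSE)
    write_report(report, config$out_dir)
  }
  list(cohort = cohort, features = features, report = report,
       config = config, hash = hash)
}
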