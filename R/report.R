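# The group contrasts mirrored from the published comparison tables:
# direction is the expected sign of (PD mean - control mean); `scored`
# marks contrasts the source study reported as significant (the pa-ta-ka
# interval variability was a null contrast there, so its direction is
# reported but not direction-scored).
group_contrast_plan <- function() {
  tibble::tribble(
    ~task,     ~feature,                ~tf, ~direction, ~scored,
    "tapping", "total_taps",            0L,  -1,  TRUE,
    "tapping", "tap_variability",       0L,   1,  TRUE,
    "tapping", "tap_variability",       1L,   1,  TRUE,
    "tapping", "tap_variability",       2L,   1,  TRUE,
    "tapping", "tap_variability",       3L,   1,  TRUE,
    "tapping", "tap_variability",       4L,   1,  TRUE,
    "tapping", "tap_variability",       5L,   1,  TRUE,
    "a",       "loudness",              0L,   1,  TRUE,
    "a",       "jitter",                0L,   1,  TRUE,
    "a",       "jitter_cv",             0L,   1,  TRUE,
    "a",       "shimmer",               0L,   1,  TRUE,
    "a",       "shimmer_cv",            0L,   1,  TRUE,
    "i",       "loudness",              0L,   1,  TRUE,
    "i",       "jitter",                0L,   1,  TRUE,
    "i",       "jitter_cv",             0L,   1,  TRUE,
    "i",       "shimmer",               0L,   1,  TRUE,
    "i",       "shimmer_cv",            0L,   1,  TRUE,
    "dadada",  "repeat_count",          0L,  -1,  TRUE,
    "dadada",  "interval_variability",  0L,   1,  TRUE,
    "pataka",  "repeat_count",          0L,  -1,  TRUE,
    "pataka",  "interval_variability",  0L,   1,  FALSE
  )
}

# vocal features carrying an interaction model (the published Table-6 set)
interaction_plan <- function() {
  tibble::tribble(
    ~task,     ~feature,
    "a",       "loudness",
    "a",       "jitter",
    "a",       "shimmer",
    "i",       "loudness",
    "i",       "jitter",
    "i",       "shimmer",
    "dadada",  "interval_variability",
    "pataka",  "interval_variability"
  )
}

#' Assemble the full results document for one cohort
#'
#' Runs the whole statistical battery on a long feature table: group
#' contrasts (published tables 2/5 analogs), the within-group
#' repeated-measures ANOVA with post hoc frames for tapping variability,
#' the time-by-group and time-by-severity mixed models, and the severity
#' correlation/regression panel. When cohort truth is supplied (simulated
#' data), a recovery section compares each estimated interaction slope with
#' the generating value.
#'
#' @param records Long feature table.
#' @param cohort Optional `tv_cohort`; enables the recovery section.
#' @param alpha Significance level annotated in the tables.
#' @param adjust Multiple-testing adjustment across the interaction panel:
#'   `"none"` (the published convention, alpha per test) or `"BH"`.
#' @return List of class `tv_report` with tibbles `group_comparison`,
#'   `anova`, `post_hoc`, `lmm_time_group`, `lmm_time_severity`,
#'   `correlation`, `recovery` (possibly zero-row), and `meta`.
#' @export
build_report <- function(records, cohort = NULL, alpha = 0.05,
                         adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  empty_meta <- tibble::tibble(n_records = nrow(records),
                               status = if (nrow(records) == 0) "no data" else "ok",
                               alpha = alpha, adjust = adjust)
  if (nrow(records) == 0) {
    return(structure(list(
      group_comparison = tibble::tibble(), anova = tibble::tibble(),
      post_hoc = tibble::tibble(), tap_trend = tibble::tibble(),
      lmm_time_group = tibble::tibble(),
      lmm_time_severity = tibble::tibble(), correlation = tibble::tibble(),
      recovery = tibble::tibble(), meta = empty_meta
    ), class = "tv_report"))
  }

  have <- dplyr::distinct(records, .data$task, .data$feature, .data$tf)
  plan <- dplyr::semi_join(group_contrast_plan(), have,
                           by = c("task", "feature", "tf"))
  grp <- dplyr::bind_rows(lapply(seq_len(nrow(plan)), function(i) {
    group_compare(records, plan$feature[i], plan$task[i], plan$tf[i])
  }))
  grp$expected_direction <- plan$direction
  grp$observed_direction <- sign(grp$mean_pd - grp$mean_control)
  grp$direction_scored <- plan$scored

  an <- list(); ph <- list()
  if (any(records$feature == "tap_variability" & records$tf %in% 1:5)) {
    for (g in intersect(c("control", "PD"), unique(records$group))) {
      res <- tf_anova(records, g, "tap_variability", task = "tapping")
      an[[g]] <- res$anova
      res$post_hoc$group <- g
      ph[[g]] <- res$post_hoc
    }
  }

  # PD tapping-variability time course: fitted linear trend of the five
  # per-frame group means (monotone in expectation; the strict stepwise
  # ordering of the estimated means is also reported)
  tap_trend <- tibble::tibble()
  if (any(records$feature == "tap_variability" & records$tf %in% 1:5 &
            records$group == "PD")) {
    agg <- aggregate_subjects(records[records$feature == "tap_variability" &
                                        records$tf %in% 1:5 &
                                        records$group == "PD", ])
    m <- tapply(agg$value, agg$tf, mean, na.rm = TRUE)
    tap_trend <- tibble::tibble(
      tf = as.integer(names(m)), mean = as.numeric(m),
      slope = unname(stats::coef(stats::lm(as.numeric(m) ~
                                             as.integer(names(m))))[2]),
      monotone = all(diff(as.numeric(m)) >= 0)
    )
  }

  iplan <- dplyr::semi_join(interaction_plan(), have[have$tf == 1, ],
                            by = c("task", "feature"))
  if (any(have$feature == "tap_variability" & have$tf == 1)) {
    iplan <- dplyr::bind_rows(
      tibble::tibble(task = "tapping", feature = "tap_variability"), iplan)
  }
  lmm_tg <- dplyr::bind_rows(lapply(seq_len(nrow(iplan)), function(i) {
    out <- fit_lmm_time_group(records, iplan$feature[i], iplan$task[i])
    out$task <- iplan$task[i]
    out
  }))
  has_pd <- sum(records$group == "PD" & !is.na(records$updrs3)) > 0
  lmm_ts <- if (has_pd) {
    dplyr::bind_rows(lapply(seq_len(nrow(iplan)), function(i) {
      out <- fit_lmm_time_severity(records, iplan$feature[i], iplan$task[i])
      out$task <- iplan$task[i]
      out
    }))
  } else tibble::tibble()
  if (adjust == "BH" && nrow(lmm_ts) > 0) {
    ix <- lmm_ts$term == "tf:updrs3"
    lmm_ts$p_adj <- NA_real_
    lmm_ts$p_adj[ix] <- stats::p.adjust(lmm_ts$p[ix], method = "BH")
  }

  corr <- if (has_pd) {
    dplyr::bind_rows(lapply(seq_len(nrow(iplan)), function(i) {
      use_tf <- if (any(have$task == iplan$task[i] &
                          have$feature == iplan$feature[i] & have$tf == 1)) 1:5 else 0L
      out <- severity_regression(records, iplan$feature[i], iplan$task[i],
                                 tf = use_tf)
      out$task <- iplan$task[i]
      out
    }))
  } else tibble::tibble()

  recovery <- tibble::tibble()
  if (!is.null(cohort) && nrow(lmm_ts) > 0) {
    tier <- attr(records, "tier") %||% "feature"
    est <- lmm_ts[lmm_ts$term == "tf:updrs3",
                  c("task", "feature", "estimate", "se", "ci_lo", "ci_hi")]
    if (identical(tier, "signal")) {
      # extracted features live on the extractor's scale, so only the sign
      # of the injected coupling is comparable
      truth_b <- cohort$truth$signal_int
      recovery <- dplyr::inner_join(est, truth_b, by = c("task", "feature"))
      recovery$true_interaction <- recovery$d_slope_du
      recovery$d_slope_du <- NULL
      recovery$comparison <- "sign_only"
      recovery$sign_recovered <- sign(recovery$estimate) ==
        sign(recovery$true_interaction) | recovery$true_interaction == 0
    } else {
      truth_b <- cohort$truth$betas[, c("task", "feature", "b_int")]
      recovery <- dplyr::inner_join(est, truth_b, by = c("task", "feature"))
      recovery$true_interaction <- recovery$b_int
      recovery$b_int <- NULL
      recovery$comparison <- "value"
      recovery$sign_recovered <- sign(recovery$estimate) ==
        sign(recovery$true_interaction) | recovery$true_interaction == 0
      recovery$ci_covers_truth <- recovery$ci_lo <= recovery$true_interaction &
        recovery$true_interaction <= recovery$ci_hi
    }
  }

  structure(list(
    group_comparison = grp,
    anova = dplyr::bind_rows(an),
    post_hoc = dplyr::bind_rows(ph),
    tap_trend = tap_trend,
    lmm_time_group = lmm_tg,
    lmm_time_severity = lmm_ts,
    correlation = corr,
    recovery = recovery,
    meta = empty_meta
  ), class = "tv_report")
}

#' @export
print.tv_report <- function(x, ...) {
  cat("<tv_report>", x$meta$status, "-", x$meta$n_records, "feature records\n")
  cat("  group contrasts:", nrow(x$group_comparison),
      "| time-severity models:",
      if (nrow(x$lmm_time_severity)) nrow(x$lmm_time_severity) / 4 else 0, "\n")
  invisible(x)
}

#' Write a report to disk
#'
#' Emits `report.json` plus one CSV per table under `tables/`.
#'
#' @param report A `tv_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(file.path(dir, "tables"), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  for (nm in names(report)) {
    if (is.data.frame(report[[nm]]) && nrow(report[[nm]]) > 0) {
      utils::write.csv(report[[nm]], file.path(dir, "tables", paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}
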