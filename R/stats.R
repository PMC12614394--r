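#' Aggregate feature records to one value per subject (and time frame)
#'
#' Features are computed per trial (hand/session for tapping, three trials
#' per session for the vocal tasks) and averaged within subject before any
#' group-level test, so each subject contributes one observation.
#'
#' @param records Long feature table (`subject_id`, `group`, `updrs3`,
#'   `task`, `trial`, `tf`, `feature`, `value`).
#' @return Tibble with one row per subject x task x feature x tf and the
#'   mean `value`.
#' @export
aggregate_subjects <- function(records) {
  records |>
    dplyr::group_by(.data$subject_id, .data$group, .data$updrs3,
                    .data$task, .data$feature, .data$tf) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
}

#' Two-group comparison of one feature
#'
#' Pooled-variance (Student) two-sample t test on per-subject means, the
#' convention matching df = 38 for 20 + 20 subjects. Order of comparison is
#' control minus PD, i.e. a negative t means the PD mean is larger.
#'
#' @param records Long feature table.
#' @param feature Feature name.
#' @param task Task name (default: any task carrying the feature).
#' @param tf Time frame to compare (`0` = whole-trial feature).
#' @return One-row tibble: `task`, `feature`, `tf`, `mean_control`,
#'   `sd_control`, `mean_pd`, `sd_pd`, `t`, `df`, `p`.
#' @export
group_compare <- function(records, feature, task = NULL, tf = 0L) {
  d <- records[records$feature == feature & records$tf == tf, ]
  if (!is.null(task)) d <- d[d$task == task, ]
  d <- aggregate_subjects(d)
  a <- d$value[d$group == "control"]
  b <- d$value[d$group == "PD"]
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  tibble::tibble(
    task = if (is.null(task)) paste(unique(d$task), collapse = "+") else task,
    feature = feature, tf = tf,
    mean_control = mean(a), sd_control = stats::sd(a),
    mean_pd = mean(b), sd_pd = stats::sd(b),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value
  )
}

#' Repeated-measures ANOVA over the five time frames
#'
#' One-way within-subject ANOVA of a feature across TF1-TF5 for one group
#' (per-subject per-TF means; subjects with incomplete frames are dropped
#' with a warning), followed by post hoc paired t tests of each later frame
#' against TF1 with Holm adjustment.
#'
#' @param records Long feature table.
#' @param group `"PD"` or `"control"`.
#' @param feature Feature name.
#' @param task Optional task restriction.
#' @return List with `anova` (one-row tibble: `F`, `df_between`,
#'   `df_within`, `p`) and `post_hoc` (tibble per frame vs TF1: `t`, `df`,
#'   `p`, `p_adj`).
#' @export
tf_anova <- function(records, group, feature, task = NULL) {
  d <- records[records$feature == feature & records$tf %in% 1:5 &
                 records$group == group, ]
  if (!is.null(task)) d <- d[d$task == task, ]
  d <- aggregate_subjects(d)
  wide <- tidyr::pivot_wider(d[, c("subject_id", "tf", "value")],
                             names_from = "tf", values_from = "value")
  complete <- stats::complete.cases(wide)
  if (!all(complete)) {
    warning(sum(!complete), " subject(s) dropped for incomplete frames")
    wide <- wide[complete, ]
  }
  if (nrow(wide) < 3L) stop("too few complete subjects", call. = FALSE)
  long <- tidyr::pivot_longer(wide, -"subject_id", names_to = "tf",
                              values_to = "value")
  long$tf <- factor(long$tf, levels = as.character(1:5))
  long$subject_id <- factor(long$subject_id)
  fit <- stats::aov(value ~ tf + Error(subject_id), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  ss_tf <- tab["tf", "Sum Sq"]
  ss_res <- tab["Residuals", "Sum Sq"]
  degenerate <- ss_tf + ss_res < 1e-12 * max(1, sum(long$value^2))
  res <- tibble::tibble(
    group = group, feature = feature,
    F = if (degenerate) 0 else tab["tf", "F value"],
    df_between = tab["tf", "Df"],
    df_within = tab["Residuals", "Df"],
    p = if (degenerate) 1 else tab["tf", "Pr(>F)"]
  )
  base <- wide[["1"]]
  ph <- lapply(2:5, function(k) {
    d <- wide[[as.character(k)]] - base
    if (stats::sd(d) < 1e-14) {
      # no within-subject change at all: by construction no evidence
      tibble::tibble(tf = k, t = 0, df = length(d) - 1, p = 1)
    } else {
      tt <- stats::t.test(wide[[as.character(k)]], base, paired = TRUE)
      tibble::tibble(tf = k, t = unname(tt$statistic),
                     df = unname(tt$parameter), p = tt$p.value)
    }
  })
  ph <- dplyr::bind_rows(ph)
  ph$p_adj <- stats::p.adjust(ph$p, method = "holm")
  list(anova = res, post_hoc = ph)
}

# shared machinery for the two interaction models
fit_lmm <- function(d, covariate, df_paper) {
  d$tf_num <- as.numeric(d$tf)
  if (length(unique(d[[covariate]])) < 2L) {
    stop("covariate '", covariate, "' is constant; interaction inestimable",
         call. = FALSE)
  }
  fml <- stats::as.formula(
    paste0("value ~ tf_num * ", covariate, " + (1 | subject_id)"))
  fit <- lmerTest::lmer(fml, data = d, REML = TRUE)
  singular <- lme4::isSingular(fit, tol = 1e-8)
  co <- summary(fit)$coefficients
  term_names <- c("intercept", "tf", covariate, paste0("tf:", covariate))
  df <- co[, "df"]
  crit <- stats::qt(0.975, df)
  vc <- as.data.frame(lme4::VarCorr(fit))
  tibble::tibble(
    term = term_names,
    estimate = co[, "Estimate"],
    se = co[, "Std. Error"],
    t = co[, "t value"],
    df = df,
    df_paper = df_paper,
    p = co[, "Pr(>|t|)"],
    p_paper = 2 * stats::pt(-abs(co[, "t value"]), df_paper),
    ci_lo = co[, "Estimate"] - crit * co[, "Std. Error"],
    ci_hi = co[, "Estimate"] + crit * co[, "Std. Error"],
    var_subject = vc$vcov[vc$grp == "subject_id"],
    var_residual = vc$vcov[vc$grp == "Residual"],
    singular = singular,
    logLik = as.numeric(stats::logLik(fit))
  )
}

#' Linear mixed model: time-by-group interaction
#'
#' `value ~ tf + group + tf:group + (1 | subject)` fitted by REML on one
#' row per subject x trial x time frame; `tf` is numeric 1..5 (a single
#' time slope) and group is coded control = 0, PD = 1. Degrees of freedom
#' and p-values use the Satterthwaite approximation; the published-table
#' convention (`df = n_subjects - 2`) is emitted alongside as `df_paper`.
#'
#' @param records Long feature table.
#' @param feature Feature name.
#' @param task Optional task restriction.
#' @return Tibble with one row per term (`intercept`, `tf`, `grp`,
#'   `tf:grp`): estimate, SE, t, df, p, 95% CI, variance components, and a
#'   singular-fit flag.
#' @export
fit_lmm_time_group <- function(records, feature, task = NULL) {
  d <- records[records$feature == feature & records$tf %in% 1:5, ]
  if (!is.null(task)) d <- d[d$task == task, ]
  d$grp <- as.numeric(d$group == "PD")
  out <- fit_lmm(d, "grp", df_paper = length(unique(d$subject_id)) - 2)
  out$feature <- feature
  out
}

#' Linear mixed model: time-by-severity interaction (PD group)
#'
#' `value ~ tf + updrs3 + tf:updrs3 + (1 | subject)` on PD subjects only,
#' with UPDRS part III entered as an uncentered numeric covariate (optional
#' centering via `center`). See [fit_lmm_time_group()] for conventions;
#' `df_paper` here is `n_PD - 1`.
#'
#' @param records Long feature table.
#' @param feature Feature name.
#' @param task Optional task restriction.
#' @param center Center UPDRS at its mean before fitting (default FALSE).
#' @return Tibble with one row per term (`intercept`, `tf`, `updrs3`,
#'   `tf:updrs3`).
#' @export
fit_lmm_time_severity <- function(records, feature, task = NULL,
                                  center = FALSE) {
  d <- records[records$feature == feature & records$tf %in% 1:5 &
                 records$group == "PD", ]
  if (!is.null(task)) d <- d[d$task == task, ]
  if (center) d$updrs3 <- d$updrs3 - mean(d$updrs3)
  out <- fit_lmm(d, "updrs3", df_paper = length(unique(d$subject_id)) - 1)
  out$feature <- feature
  out
}

#' Severity correlation and simple regression
#'
#' Pearson correlation between a feature and UPDRS part III over PD
#' observations (pooled across trials and frames at the subject x trial x
#' frame level), with the least-squares coefficient of determination
#' (`r2 = r^2`) and the correlation-test p-value.
#'
#' @param records Long feature table.
#' @param feature Feature name.
#' @param task Optional task restriction.
#' @param tf Frames to pool (default 1:5; use 0 for whole-trial features).
#' @return One-row tibble: `feature`, `r`, `r2`, `p`, `slope`, `n`.
#' @export
severity_regression <- function(records, feature, task = NULL, tf = 1:5) {
  d <- records[records$feature == feature & records$tf %in% tf &
                 records$group == "PD" & !is.na(records$value), ]
  if (!is.null(task)) d <- d[d$task == task, ]
  if (stats::sd(d$value) == 0 || stats::sd(d$updrs3) == 0) {
    stop("zero variance; correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(d$value, d$updrs3)
  r <- unname(ct$estimate)
  slope <- unname(stats::coef(stats::lm(value ~ updrs3, data = d))[2])
  tibble::tibble(feature = feature, r = r, r2 = r^2, p = ct$p.value,
                 slope = slope, n = nrow(d))
}
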