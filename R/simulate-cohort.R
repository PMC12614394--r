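#' Population-level feature model used by the paper-like scenario
#'
#' For persons with PD the per-time-frame expectation of each vocal feature
#' follows `b0 + b_tf*tf + b_sev*updrs3 + b_int*tf*updrs3`; the coefficient
#' sets are the published interaction-model estimates for each task
#' (loudness declining faster, jitter/shimmer rising faster at higher UPDRS
#' part III). Control expectations are anchored at the published group
#' means with a zero time slope. Between-subject scales (`sigma_u`) are set
#' so the group-contrast t statistics match the published magnitudes
#' (floored at 3); within-trial per-frame dispersion (`sigma_e`) is larger
#' in the PD group, which is what carries the elevated jitter/shimmer
#' variability (CV) of that group.
#'
#' @return A tibble with one row per vocal feature: `task`, `feature`, `b0`,
#'   `b_tf`, `b_sev`, `b_int` (fixed effects of the PD model), `sigma_e_control`,
#'   `sigma_e_pd` (within-trial per-frame dispersion), `control_mean` (control
#'   expectation, flat in time), `floor` (lower bound for strictly positive
#'   quantities), `t_anchor` (the published group-contrast t magnitude, floored
#'   at 3, from which `sigma_u` is derived), and the derived `sigma_u`.
#' @export
feature_betas <- function() {
  b <- tibble::tribble(
    ~task,     ~feature,   ~b0,     ~b_tf,      ~b_sev,     ~b_int,      ~sigma_e_control, ~sigma_e_pd, ~control_mean, ~floor,  ~t_anchor,
    "a",       "loudness", 2.319,   0.0825,     0.00123,   -0.00830,     0.10,             0.20,        1.573,         -Inf,    4.514,
    "a",       "jitter",   0.00929, -0.000456,  -0.000111,  0.000106,    0.0012,           0.0028,      0.0074,        5e-4,    4.647,
    "a",       "shimmer",  0.395,   -0.0183,    -0.000815,  0.00338,     0.05,             0.10,        0.477,         0.01,    3,
    "i",       "loudness", 1.341,   0.0787,     0.00238,   -0.00492,     0.08,             0.16,        1.082,         -Inf,    3.225,
    "i",       "jitter",   0.0112,  -0.00232,   -0.000357,  0.000196,    0.0012,           0.0028,      0.0071,        5e-4,    3,
    "i",       "shimmer",  0.393,   -0.0470,    -0.00823,   0.00498,     0.05,             0.10,        0.330,         0.01,    3,
    "dadada",  "interval_variability", 1.474, -0.0433, 0.0462, 0.00307,  0.35,             0.60,        1.931,         0.01,    6.325,
    "pataka",  "interval_variability", 0.424,  0.724,  0.0961, -0.0194,  0.70,             1.00,        3.300,         0.01,    3
  )
  # between-subject scale chosen so the analytic z of the group contrast
  # (PD at UPDRS 22.10, mid frame, vs control; n = 20 + 20; severity-path
  # variance included) equals the published |t|, floored at 3
  pd_mean <- b$b0 + 3 * b$b_tf + (b$b_sev + 3 * b$b_int) * 22.10
  diff <- pd_mean - b$control_mean
  sig_sev <- abs(b$b_sev + 3 * b$b_int) * 10.64
  b$sigma_u <- sqrt(pmax((20 * diff^2 / b$t_anchor^2 - sig_sev^2) / 2,
                         (0.03 * abs(pd_mean))^2))
  b
}

# Whole-trial (tf = 0) count features: published group means/SDs.
count_feature_moments <- function() {
  tibble::tribble(
    ~task,    ~feature,       ~mean_control, ~sd_control, ~mean_pd, ~sd_pd,
    "dadada", "repeat_count", 40.067,        4.623,       36.225,   5.329,
    "pataka", "repeat_count", 41.010,        7.011,       37.442,   5.475
  )
}

#' Sample a synthetic cohort with known ground truth
#'
#' Draws subject profiles (20 PD / 20 control by default) and the per-subject
#' generator parameters ("truth") that every downstream simulator uses. PD
#' UPDRS part III scores come from a normal distribution with the published
#' mean 22.10 and SD 10.64, truncated to `[5, 60]`; ages use the published
#' group means/SDs. Under `scenario = "paper_like"` severity couples
#' linearly into the tapping and vocal dynamics; under `"null_interaction"`
#' every time-by-severity (and time-by-group) coupling is exactly zero and
#' the generating distribution of each feature is identical across UPDRS
#' values conditional on time frame, which is the regime used for type-I
#' error calibration.
#'
#' @param n_pd,n_control Group sizes (positive integers).
#' @param scenario `"paper_like"` or `"null_interaction"`.
#' @param seed Master seed; all per-trial substreams derive from it.
#' @return A list of class `tv_cohort` with elements `profiles` (tibble:
#'   `subject_id`, `group`, `updrs3`, `hy`, `age`, `sex`), and `truth` (see
#'   Details). `truth` carries `betas` (population coefficients), `subjects`
#'   (per-subject signal-tier parameters), `rand_int` (per-subject random
#'   intercepts of the feature model), `scenario`, and `seed`.
#' @examples
#' coh <- sample_cohort(5, 5, seed = 1)
#' coh$profiles
#' @export
sample_cohort <- function(n_pd = 20, n_control = 20,
                          scenario = c("paper_like", "null_interaction"),
                          seed = 1L) {
  scenario <- match.arg(scenario)
  if (n_pd < 1 || n_control < 1) {
    stop("group sizes must be positive", call. = FALSE)
  }
  null_int <- scenario == "null_interaction"

  profiles <- with_local_seed(derive_seed(seed, "profiles"), {
    pd <- tibble::tibble(
      subject_id = sprintf("pd%02d", seq_len(n_pd)),
      group = "PD",
      updrs3 = round(rnorm_clamped(n_pd, 22.10, 10.64, 5, 60)),
      hy = sample(c(1.5, 2, 2.5, 3), n_pd, replace = TRUE,
                  prob = c(0.20, 0.25, 0.35, 0.20)),
      age = round(rnorm_clamped(n_pd, 68.30, 6.30, 45, 90)),
      sex = sample(c("F", "M"), n_pd, replace = TRUE, prob = c(0.85, 0.15))
    )
    ct <- tibble::tibble(
      subject_id = sprintf("hc%02d", seq_len(n_control)),
      group = "control",
      updrs3 = NA_real_,
      hy = NA_real_,
      age = round(rnorm_clamped(n_control, 33.55, 7.85, 19, 70)),
      sex = sample(c("F", "M"), n_control, replace = TRUE)
    )
    dplyr::bind_rows(pd, ct)
  })

  subjects <- with_local_seed(derive_seed(seed, "truth"), {
    n <- nrow(profiles)
    pd <- profiles$group == "PD"
    u <- ifelse(pd, profiles$updrs3, 0)
    # severity couplings vanish entirely under the null scenario
    k <- if (null_int) 0 else 1
    tibble::tibble(
      subject_id = profiles$subject_id,
      # -- tapping: lognormal inter-tap intervals, per-frame SD
      #    sigma0 + tf_slope * (tf - 1)
      tap_mu = ifelse(pd,
        rnorm_clamped(n, 0.35 + k * 0.009 * u + (1 - k) * 0.20, 0.06, 0.20, 1.20),
        rnorm_clamped(n, 0.25, 0.03, 0.15, 0.40)),
      tap_sigma0 = ifelse(pd,
        rnorm_clamped(n, 0.030 + k * 0.0032 * u + (1 - k) * 0.071, 0.015, 0.010, 0.40),
        rnorm_clamped(n, 0.0238, 0.008, 0.005, 0.10)),
      tap_tf_slope = ifelse(pd,
        rnorm_clamped(n, 0.002 + k * 0.00035 * u, 0.002, 0, 0.05),
        rnorm_clamped(n, 0.002, 0.001, 0, 0.02)),
      # -- phonation signal tier (relative perturbations per glottal cycle)
      f0 = runif(n, 150, 220),
      jitter0 = rnorm_clamped(n, 0.006 + k * ifelse(pd, 0.0002 * u, 0), 0.002,
                              0.002, 0.05),
      jitter_slope = ifelse(pd, -0.0002 + k * 0.00002 * u, 0),
      shimmer0 = rnorm_clamped(n, 0.04 + k * ifelse(pd, 0.001 * u, 0), 0.01,
                               0.01, 0.30),
      shimmer_slope = ifelse(pd, -0.001 + k * 0.0001 * u, 0),
      amp0 = ifelse(pd,
        rnorm_clamped(n, 0.30, 0.05, 0.10, 0.45),
        rnorm_clamped(n, 0.25, 0.05, 0.10, 0.45)),
      amp_slope = ifelse(pd, 0.005 - k * 0.0005 * u,
                         rnorm_clamped(n, 0.005, 0.003, -0.01, 0.02)),
      # -- syllable trains: inter-onset-interval mean and SD
      ioi_mean = ifelse(pd,
        rnorm_clamped(n, 0.132 + k * 0.0004 * u + (1 - k) * 0.009, 0.006, 0.115, 0.25),
        rnorm_clamped(n, 0.125, 0.005, 0.110, 0.20)),
      ioi_sd0 = ifelse(pd,
        rnorm_clamped(n, 0.008 + k * 0.0006 * u + (1 - k) * 0.013, 0.002, 0.003, 0.08),
        rnorm_clamped(n, 0.008, 0.002, 0.003, 0.05))
    )
  })

  betas <- feature_betas()
  if (null_int) {
    betas$b_sev <- 0
    betas$b_int <- 0
    # identical conditional distributions across severity => same dispersion
    betas$sigma_e_pd <- betas$sigma_e_control
    # and the PD expectation pinned at the control level
    betas$b0 <- betas$control_mean
    betas$b_tf <- 0
  }

  rand_int <- with_local_seed(derive_seed(seed, "randint"), {
    tidyr::expand_grid(
      subject_id = profiles$subject_id,
      dplyr::distinct(betas, .data$task, .data$feature)
    ) |>
      dplyr::left_join(betas[, c("task", "feature", "sigma_u", "floor")],
                       by = c("task", "feature")) |>
      # intercepts of strictly positive features are kept within 2 SD so a
      # subject's mean level cannot degenerate towards zero (where the CV
      # of the feature would blow up)
      dplyr::mutate(u = rnorm(dplyr::n(), 0, .data$sigma_u),
                    u = ifelse(is.finite(.data$floor),
                               pmin(pmax(.data$u, -2 * .data$sigma_u),
                                    2 * .data$sigma_u),
                               .data$u)) |>
      dplyr::select(-"sigma_u", -"floor")
  })

  # signal-tier population couplings: how each per-frame dynamic changes per
  # UPDRS point (loudness on the amplitude scale, hence sign-only downstream)
  k <- if (null_int) 0 else 1
  signal_int <- tibble::tribble(
    ~task,    ~feature,               ~d_slope_du,
    "a",      "jitter",               k * 2e-5,
    "i",      "jitter",               k * 2e-5,
    "a",      "shimmer",              k * 1e-4,
    "i",      "shimmer",              k * 1e-4,
    "a",      "loudness",             k * -5e-4,
    "i",      "loudness",             k * -5e-4,
    "dadada", "interval_variability", 0,
    "pataka", "interval_variability", 0
  )

  structure(
    list(
      profiles = profiles,
      truth = list(
        scenario = scenario,
        seed = as.integer(seed),
        betas = betas,
        counts = count_feature_moments(),
        subjects = subjects,
        rand_int = rand_int,
        signal_int = signal_int
      )
    ),
    class = "tv_cohort"
  )
}

#' @export
print.tv_cohort <- function(x, ...) {
  cat("<tv_cohort> ", sum(x$profiles$group == "PD"), " PD / ",
      sum(x$profiles$group == "control"), " control, scenario '",
      x$truth$scenario, "', seed ", x$truth$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate one finger-tapping trial
#'
#' Generates a 20 s stream of alternating left/right tap events. Inter-tap
#' intervals are lognormal with subject mean `tap_mu` and a per-frame SD of
#' `tap_sigma0 + tap_tf_slope * (tf - 1)`, so regularity degrades over the
#' trial; under the paper-like scenario both the baseline SD and its slope
#' grow with UPDRS part III. A small fraction of events (default 2%) is
#' injected as same-side duplicates to exercise the alternation filter;
#' injected events are flagged in the returned table.
#'
#' @param profile One row of the cohort `profiles` tibble.
#' @param truth The cohort `truth` list.
#' @param hand `"left"` or `"right"`.
#' @param session Session index (1 or 2).
#' @param duplicate_frac Fraction of taps followed by an injected
#'   duplicate-side event.
#' @return A tap-trial list: `subject_id`, `hand`, `session`, `duration`,
#'   and `events` (tibble `t_sec`, `side`, `injected`).
#' @export
simulate_tap_trial <- function(profile, truth, hand = "right", session = 1L,
                               duplicate_frac = 0.02) {
  pars <- truth$subjects[truth$subjects$subject_id == profile$subject_id, ]
  if (nrow(pars) != 1L) stop("unknown subject ", profile$subject_id, call. = FALSE)
  seed <- derive_seed(truth$seed, profile$subject_id, "tap", hand, session)
  duration <- 20
  spec <- time_frames("tapping")
  with_local_seed(seed, {
    # first tap opens the trial; intervals are drawn in chunks whose SD is
    # the per-frame sigma of the frame containing the tap that opens them
    times <- 0
    t <- 0
    m <- pars$tap_mu
    repeat {
      k <- assign_time_frame(min(t, duration - 1e-9), spec)
      sigma <- pars$tap_sigma0 + pars$tap_tf_slope * (k - 1)
      sdlog2 <- log(1 + (sigma / m)^2)
      cand <- t + cumsum(stats::rlnorm(16, meanlog = log(m) - sdlog2 / 2,
                                       sdlog = sqrt(sdlog2)))
      lim <- min(spec$end[k], duration)
      take <- cand[cand <= lim]
      if (length(take) == 0L) {
        if (cand[1] > duration) break
        take <- cand[1]  # interval straddling the frame boundary
      }
      times <- c(times, take)
      t <- take[length(take)]
      if (t >= duration) break
    }
    n <- length(times)
    ev <- tibble::tibble(t_sec = times,
                         side = rep(c("left", "right"), length.out = n),
                         injected = FALSE)
    # inject duplicate-side events shortly after a random subset of taps
    if (duplicate_frac > 0 && n > 2) {
      idx <- which(runif(n) < duplicate_frac)
      idx <- idx[idx < n]
      if (length(idx) > 0) {
        # placed strictly between the tap and its successor, so the filter
        # drops exactly the injected events
        dup <- tibble::tibble(
          t_sec = ev$t_sec[idx] +
            runif(length(idx), 0.3, 0.7) * (ev$t_sec[idx + 1L] - ev$t_sec[idx]),
          side = ev$side[idx],
          injected = TRUE
        )
        ev <- dplyr::arrange(dplyr::bind_rows(ev, dup), .data$t_sec)
      }
    }
    list(subject_id = profile$subject_id, hand = hand, session = session,
         duration = duration, events = ev)
  })
}

#' Simulate a long feature table directly from the linear feature model
#'
#' Draws per-trial, per-time-frame feature values straight from the
#' generating linear structure (fixed effects of [feature_betas()], a
#' subject random intercept, and i.i.d. per-frame noise), bypassing audio
#' synthesis. This is the generator tier used for the statistical
#' calibration and recovery suites, where hundreds of cohorts are needed;
#' the signal tier (audio/taps) realises the same structure and is validated
#' separately by the extraction-recovery tests. Whole-trial count features
#' (`repeat_count`, tf = 0) and the full tapping pipeline (simulated tap
#' events run through [tap_summary()]) are included so every published
#' group contrast can be evaluated.
#'
#' @param cohort A `tv_cohort` from [sample_cohort()].
#' @param n_sessions Sessions per subject (default 2, as in the protocol).
#' @param n_trials Trials per vocal task and session (default 3).
#' @param include_taps Run the tap simulator + extraction pipeline too.
#' @return Long tibble: `subject_id`, `group`, `updrs3`, `task`, `trial`,
#'   `tf` (0 = whole trial), `feature`, `value`.
#' @export
simulate_feature_table <- function(cohort, n_sessions = 2, n_trials = 3,
                                   include_taps = TRUE) {
  profiles <- cohort$profiles
  truth <- cohort$truth
  betas <- truth$betas
  upd <- ifelse(profiles$group == "PD", profiles$updrs3, 0)
  names(upd) <- profiles$subject_id

  grid <- tidyr::expand_grid(
    subject_id = profiles$subject_id,
    session = seq_len(n_sessions),
    rep = seq_len(n_trials),
    betas[, c("task", "feature")],
    tf = 1:5
  ) |>
    dplyr::left_join(profiles[, c("subject_id", "group", "updrs3")],
                     by = "subject_id") |>
    dplyr::left_join(betas, by = c("task", "feature")) |>
    dplyr::left_join(truth$rand_int, by = c("subject_id", "task", "feature"))

  vocal <- with_local_seed(derive_seed(truth$seed, "featuretier"), {
    pd <- grid$group == "PD"
    mu <- ifelse(pd,
      grid$b0 + grid$b_tf * grid$tf + grid$b_sev * grid$updrs3 +
        grid$b_int * grid$tf * grid$updrs3,
      grid$control_mean)
    sigma_e <- ifelse(pd, grid$sigma_e_pd, grid$sigma_e_control)
    grid$value <- pmax(mu + grid$u + rnorm(nrow(grid), 0, sigma_e),
                       grid$floor)
    grid$trial <- paste0("s", grid$session, "_t", grid$rep)
    grid[, c("subject_id", "group", "updrs3", "task", "trial", "tf",
             "feature", "value")]
  })

  counts <- with_local_seed(derive_seed(truth$seed, "counts"), {
    cg <- tidyr::expand_grid(
      subject_id = profiles$subject_id,
      session = seq_len(n_sessions),
      rep = seq_len(n_trials),
      truth$counts
    ) |>
      dplyr::left_join(profiles[, c("subject_id", "group", "updrs3")],
                       by = "subject_id")
    pd <- cg$group == "PD"
    cg$value <- round(rnorm(nrow(cg),
                            ifelse(pd, cg$mean_pd, cg$mean_control),
                            ifelse(pd, cg$sd_pd, cg$sd_control)))
    cg$trial <- paste0("s", cg$session, "_t", cg$rep)
    cg$tf <- 0L
    cg[, c("subject_id", "group", "updrs3", "task", "trial", "tf",
           "feature", "value")]
  })

  # whole-trial aggregates, derived exactly as the extraction tier derives
  # them: tf0 value = mean of the five per-TF values; jitter/shimmer
  # variability = coefficient of variation of the five per-TF values
  whole <- vocal |>
    dplyr::group_by(.data$subject_id, .data$group, .data$updrs3, .data$task,
                    .data$trial, .data$feature) |>
    dplyr::summarise(mean_v = mean(.data$value),
                     cv = coefficient_of_variation(.data$value),
                     .groups = "drop")
  tf0 <- whole |>
    dplyr::transmute(.data$subject_id, .data$group, .data$updrs3, .data$task,
                     .data$trial, tf = 0L, .data$feature, value = .data$mean_v)
  cvs <- whole |>
    dplyr::filter(.data$feature %in% c("jitter", "shimmer")) |>
    dplyr::transmute(.data$subject_id, .data$group, .data$updrs3, .data$task,
                     .data$trial, tf = 0L,
                     feature = paste0(.data$feature, "_cv"), value = .data$cv)

  out <- dplyr::bind_rows(vocal, tf0, cvs, counts)

  if (include_taps) {
    taps <- lapply(seq_len(nrow(profiles)), function(i) {
      prof <- profiles[i, ]
      rows <- lapply(seq_len(n_sessions), function(s) {
        dplyr::bind_rows(
          tap_summary(simulate_tap_trial(prof, truth, "left", s)),
          tap_summary(simulate_tap_trial(prof, truth, "right", s))
        )
      })
      dplyr::bind_rows(rows) |>
        dplyr::mutate(group = prof$group, updrs3 = prof$updrs3)
    })
    out <- dplyr::bind_rows(out, dplyr::bind_rows(taps))
  }
  out <- dplyr::as_tibble(out[, c("subject_id", "group", "updrs3", "task",
                                  "trial", "tf", "feature", "value")])
  attr(out, "tier") <- "feature"
  out
}
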