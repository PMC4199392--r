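# Design constants of the rhythmic tone-categorization experiments.
# All times in ms, 0-based at the first reference onset.
BEAT_PERIOD_MS <- 667
TONE_DURATION_MS <- 100
F0_HZ <- 440
GAUSS_JITTER_SD_MS <- 67   # s.d. of the approximately-Gaussian jitter (exp1/exp3)
UNIFORM_JITTER_MS <- 67    # half-width of the uniform jitter (exp2)
JITTER_CAP_MS <- 141       # hard cap so targets and distractors never overlap
N_BEATS <- 13              # theoretical reference beats 0..12 cover every tone

#' Fixed design constants of the experiments
#'
#' Beat period, tone duration, reference frequency and jitter bounds shared by
#' all three experiment layouts.
#'
#' @return A named list: `beat_period_ms`, `tone_duration_ms`, `f0_hz`,
#'   `gauss_jitter_sd_ms`, `uniform_jitter_ms`, `jitter_cap_ms`, `n_beats`.
#' @export
#' @examples
#' design_constants()$beat_period_ms
design_constants <- function() {
  list(
    beat_period_ms = BEAT_PERIOD_MS,
    tone_duration_ms = TONE_DURATION_MS,
    f0_hz = F0_HZ,
    gauss_jitter_sd_ms = GAUSS_JITTER_SD_MS,
    uniform_jitter_ms = UNIFORM_JITTER_MS,
    jitter_cap_ms = JITTER_CAP_MS,
    n_beats = N_BEATS
  )
}

#' Theoretical reference beat
#'
#' Arithmetic progression of beat times at a fixed period, the scaffold on
#' which tones, taps and the nonmotor simultaneity control are aligned.
#'
#' @param period_ms Beat period in ms (default 667, i.e. 1.5 Hz).
#' @param n_beats Number of beats (>= 1).
#' @param t0 Time of the first beat in ms.
#' @return Numeric vector of beat times in ms, length `n_beats`.
#' @export
#' @examples
#' make_reference_beat(667, 3, 0)
make_reference_beat <- function(period_ms = BEAT_PERIOD_MS, n_beats = N_BEATS,
                                t0 = 0) {
  if (!is.numeric(period_ms) || length(period_ms) != 1 || period_ms <= 0) {
    abort("`period_ms` must be a single positive number.",
          class = "tapgain_invalid_argument")
  }
  if (!is.numeric(n_beats) || length(n_beats) != 1 || n_beats < 1 ||
      n_beats != round(n_beats)) {
    abort("`n_beats` must be a single integer >= 1.",
          class = "tapgain_invalid_argument")
  }
  t0 + period_ms * (seq_len(n_beats) - 1)
}

# Per-experiment nominal tone layout (one trial). References are the first
# four beats; the target and distractor streams interleave at half-period
# offset. In exp3 the physical sequence of exp1 keeps its onsets but the role
# labels are swapped, so targets sit in antiphase with the reference beat.
tone_layout <- function(experiment) {
  half <- BEAT_PERIOD_MS / 2
  first <- 4 * BEAT_PERIOD_MS
  ref <- tibble(role = "reference", index_in_role = 1:4,
                nominal_onset_ms = BEAT_PERIOD_MS * (0:3))
  on_beat <- first + BEAT_PERIOD_MS * (0:7)
  off_beat <- on_beat + half
  lay <- switch(experiment,
    exp1 = bind_rows(
      ref,
      tibble(role = "target", index_in_role = 1:8, nominal_onset_ms = on_beat),
      tibble(role = "distractor", index_in_role = 1:8,
             nominal_onset_ms = off_beat)
    ),
    exp2 = bind_rows(
      ref,
      tibble(role = "target", index_in_role = 1:8, nominal_onset_ms = on_beat),
      tibble(role = "distractor", index_in_role = 1:9,
             nominal_onset_ms = first - half + BEAT_PERIOD_MS * (0:8))
    ),
    exp3 = bind_rows(
      ref,
      tibble(role = "distractor", index_in_role = 1:8,
             nominal_onset_ms = on_beat),
      tibble(role = "target", index_in_role = 1:8, nominal_onset_ms = off_beat)
    ),
    abort(paste0("Unknown experiment: ", experiment),
          class = "tapgain_invalid_argument")
  )
  arrange(lay, .data$nominal_onset_ms)
}

# Gaussian jitter truncated strictly inside +/- cap, by rejection.
rtrunc_gauss <- function(n, sd, cap) {
  x <- rnorm(n, 0, sd)
  bad <- which(abs(x) >= cap)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), 0, sd)
    bad <- bad[abs(x[bad]) >= cap]
  }
  x
}

check_jitter_condition <- function(experiment, jitter_condition) {
  if (is.null(jitter_condition)) {
    return("td")
  }
  if (!jitter_condition %in% c("TD", "Td", "tD", "td")) {
    abort("`jitter_condition` must be one of 'TD', 'Td', 'tD', 'td'.",
          class = "tapgain_invalid_argument")
  }
  if (experiment != "exp2" && jitter_condition != "td") {
    abort("The 2x2 rhythmicity factor (jitter_condition != 'td') exists only in exp2.",
          class = "tapgain_invalid_argument")
  }
  jitter_condition
}

#' Generate tone sequences for one or many trials
#'
#' Builds complete tone tables for the three experiment layouts: four
#' reference tones at the 667 ms beat, then interleaved target and distractor
#' streams (8 targets and 8 distractors in exp1/exp3; 8 targets and 9
#' distractors in exp2). Target and distractor log2-frequencies are drawn
#' from a normal law with s.d. `sigma_f`; targets are recentred so that the
#' per-trial target mean is exactly the signed titrated offset (the task
#' statistic the staircase controls), while distractors have zero mean in
#' expectation (noninformative) but are not recentred within the trial,
#' which keeps every per-position regressor of the reverse-correlation
#' design identifiable. Onset jitter is approximately Gaussian
#' (s.d. 67 ms, hard-capped below 141 ms) in exp1/exp3 and uniform on
#' +/- 67 ms in exp2, applied to the streams selected by `jitter_condition`.
#'
#' @param n_trials Number of trials to generate.
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`.
#' @param condition `"listen"` or `"motor"`.
#' @param jitter_condition For exp2, one of `"TD"`, `"Td"`, `"tD"`, `"td"`
#'   (uppercase = rhythmic stream, lowercase = jittered; `"td"` = both
#'   jittered). exp1/exp3 always use their single jittered regime `"td"`.
#' @param delta Magnitude of the titrated target-mean offset in log2 units;
#'   its sign is balanced 50/50 across trials (or set via `delta_signs`).
#' @param sigma_f Per-tone frequency s.d. in log2 units (default 0.2).
#' @param delta_signs Optional vector of +/- 1 of length `n_trials`.
#' @param trial_id_start First trial id.
#' @param seed Optional integer seed; the draw is bitwise-reproducible.
#' @return A tibble, one row per tone, with trial-level columns
#'   (`trial_id`, `experiment`, `condition`, `jitter_condition`,
#'   `f_tar_mean_log2`) and per-tone columns (`role`, `index_in_role`,
#'   `nominal_onset_ms`, `jitter_ms`, `onset_ms`, `duration_ms`, `f_log2`,
#'   `f_log2_raw`). `f_log2_raw` is the draw before per-trial recentring.
#' @export
#' @examples
#' tones <- generate_trials(2, "exp1", "listen", delta = 0.1, seed = 1)
#' dplyr::count(tones, role)
generate_trials <- function(n_trials, experiment = c("exp1", "exp2", "exp3"),
                            condition = c("listen", "motor"),
                            jitter_condition = NULL, delta = 0.1,
                            sigma_f = 0.2, delta_signs = NULL,
                            trial_id_start = 1L, seed = NULL) {
  experiment <- match.arg(experiment)
  condition <- match.arg(condition)
  jitter_condition <- check_jitter_condition(experiment, jitter_condition)
  if (!is.numeric(n_trials) || length(n_trials) != 1 || n_trials < 0 ||
      n_trials != round(n_trials)) {
    abort("`n_trials` must be a single non-negative integer.",
          class = "tapgain_invalid_argument")
  }
  if (!is.numeric(sigma_f) || sigma_f < 0) {
    abort("`sigma_f` must be >= 0.", class = "tapgain_invalid_argument")
  }
  if (!is.numeric(delta) || abs(delta) > 4) {
    abort("`delta` beyond 4 log2 units would put mean target frequencies outside the audible pure-tone range.",
          class = "tapgain_invalid_argument")
  }
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_trials(
      n_trials, experiment, condition, jitter_condition, delta, sigma_f,
      delta_signs, trial_id_start, seed = NULL
    )))
  }

  lay <- tone_layout(experiment)
  m <- nrow(lay)
  n_tar <- sum(lay$role == "target")
  n_dis <- sum(lay$role == "distractor")
  n_trials <- as.integer(n_trials)

  if (is.null(delta_signs)) {
    delta_signs <- rep_len(c(1, -1), n_trials)
    if (n_trials > 1) delta_signs <- sample(delta_signs)
  } else if (length(delta_signs) != n_trials ||
             !all(delta_signs %in% c(-1, 1))) {
    abort("`delta_signs` must be +/- 1 and match `n_trials`.",
          class = "tapgain_invalid_argument")
  }

  ids <- trial_id_start + seq_len(n_trials) - 1L
  role <- rep(lay$role, times = n_trials)
  is_tar <- role == "target"
  is_dis <- role == "distractor"

  # Jitter per regime; references are never jittered.
  jit <- numeric(m * n_trials)
  tar_jittered <- substr(jitter_condition, 1, 1) == "t"
  dis_jittered <- substr(jitter_condition, 2, 2) == "d"
  if (experiment %in% c("exp1", "exp3")) {
    jit[is_tar] <- rtrunc_gauss(n_tar * n_trials, GAUSS_JITTER_SD_MS,
                                JITTER_CAP_MS)
    jit[is_dis] <- rtrunc_gauss(n_dis * n_trials, GAUSS_JITTER_SD_MS,
                                JITTER_CAP_MS)
  } else {
    if (tar_jittered) {
      jit[is_tar] <- runif(n_tar * n_trials, -UNIFORM_JITTER_MS,
                           UNIFORM_JITTER_MS)
    }
    if (dis_jittered) {
      jit[is_dis] <- runif(n_dis * n_trials, -UNIFORM_JITTER_MS,
                           UNIFORM_JITTER_MS)
    }
  }

  # Target frequencies: raw draws around the per-trial titrated mean, then
  # recentred so the per-trial sample mean is exactly +/- delta (the task
  # statistic the staircase controls). Distractor frequencies are drawn with
  # zero mean in expectation but are NOT recentred within the trial: an
  # exact per-trial zero sum would make the per-position distractor
  # regressors of the reverse-correlation design linearly dependent and the
  # pooled distractor gain unidentifiable. Within each trial the rows of a
  # role appear in a fixed order, so a role-by-trial matrix reshape gives
  # the per-trial means.
  recentre <- function(n_role, mean_by_trial) {
    eps <- rnorm(n_role * n_trials, 0, sigma_f)
    if (n_trials == 0) {
      return(list(raw = numeric(0), centred = numeric(0)))
    }
    em <- matrix(eps, nrow = n_role)
    centred <- em - rep(colMeans(em), each = n_role)
    mu <- rep(mean_by_trial, each = n_role)
    list(raw = mu + eps, centred = mu + as.numeric(centred))
  }
  tar_mean <- delta_signs * delta
  tar_f <- recentre(n_tar, tar_mean)
  dis_draw <- rnorm(n_dis * n_trials, 0, sigma_f)
  dis_f <- list(raw = dis_draw, centred = dis_draw)

  f_log2 <- numeric(m * n_trials)
  f_raw <- numeric(m * n_trials)
  f_log2[is_tar] <- tar_f$centred
  f_raw[is_tar] <- tar_f$raw
  f_log2[is_dis] <- dis_f$centred
  f_raw[is_dis] <- dis_f$raw

  nominal <- rep(lay$nominal_onset_ms, times = n_trials)
  tibble(
    trial_id = rep(ids, each = m),
    experiment = experiment,
    condition = condition,
    jitter_condition = jitter_condition,
    f_tar_mean_log2 = rep(tar_mean, each = m),
    role = role,
    index_in_role = rep(lay$index_in_role, times = n_trials),
    nominal_onset_ms = nominal,
    jitter_ms = jit,
    onset_ms = nominal + jit,
    duration_ms = TONE_DURATION_MS,
    f_log2 = f_log2,
    f_log2_raw = f_raw
  )
}

#' Generate a single trial
#'
#' Convenience wrapper around [generate_trials()] for one trial.
#'
#' @inheritParams generate_trials
#' @param delta_sign Sign (+1 or -1) of the target-mean offset, i.e. the
#'   trial's correct answer; drawn at random if `NULL`.
#' @param trial_id Trial id of the generated trial.
#' @return A tibble of tones, as [generate_trials()].
#' @export
generate_trial <- function(experiment = c("exp1", "exp2", "exp3"),
                           condition = c("listen", "motor"),
                           jitter_condition = NULL, delta = 0.1,
                           sigma_f = 0.2, delta_sign = NULL, trial_id = 1L,
                           seed = NULL) {
  if (is.null(delta_sign)) {
    signs <- NULL
  } else {
    signs <- delta_sign
  }
  generate_trials(1L, experiment, condition, jitter_condition, delta, sigma_f,
                  delta_signs = signs, trial_id_start = trial_id, seed = seed)
}

#' Nominal beat phase of each tone
#'
#' Phase of the nominal (unjittered) onset relative to the 667 ms reference
#' beat: 0 rad for on-beat roles, pi for antiphase roles. Realized onsets
#' deviate from this by `2 * pi * jitter_ms / 667`.
#'
#' @param tones A tone tibble from [generate_trials()].
#' @return `tones` with an added `nominal_phase_rad` column in `[0, 2 * pi)`.
#' @export
nominal_phase <- function(tones) {
  validate_tones(tones)
  mutate(tones, nominal_phase_rad =
           2 * pi * (.data$nominal_onset_ms %% BEAT_PERIOD_MS) /
           BEAT_PERIOD_MS)
}

#' Trial-level summary of a tone table
#'
#' @param tones A tone tibble from [generate_trials()].
#' @return One row per trial with the trial-level columns.
#' @export
trial_summary <- function(tones) {
  distinct(tones, .data$trial_id, .data$experiment, .data$condition,
           .data$jitter_condition, .data$f_tar_mean_log2)
}
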