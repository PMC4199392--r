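#' Parameters of the rhythmic-gain synthetic observer
#'
#' The generative observer assigns each target or distractor tone a sensory
#' gain that fluctuates along a cycle locked to its own motor acts (motor
#' condition) or to a covert beat-locked attention cycle (listen condition):
#' `g_k = g_role * (1 + m * cos(phi_k - pref_phase_rad))`. The probability of
#' answering "high" is `pnorm(sum(g_k * f_k) + bias_b)` and the choice is a
#' Bernoulli draw. Tapping is modelled as one intended press per beat from
#' the second reference beat, with a constant lag, white timing noise, slow
#' AR(1) wander, and rare misses.
#'
#' @param g_target,g_distractor Sensory gain per unit log2-frequency for
#'   targets and distractors.
#' @param bias_b Additive response bias towards "high".
#' @param mod_depth_m Motor-locked modulation depth in `[0, 1]`.
#' @param pref_phase_rad Phase of maximal gain within the cycle (radians).
#' @param listen_mod_depth Depth of the covert beat-locked modulation in the
#'   listen condition, in `[0, 1]`.
#' @param motor_sd_ms White tap-timing noise s.d. (ms).
#' @param motor_lag_ms Constant tap lag relative to the beat (ms).
#' @param motor_drift_sd_ms Innovation s.d. of the slow AR(1) tap wander (ms).
#' @param motor_drift_rho AR(1) coefficient of the tap wander in `[0, 1)`.
#' @param miss_prob Probability that an intended press is not recorded.
#' @return An object of class `observer_params`.
#' @export
#' @examples
#' observer_params(g_target = 1, mod_depth_m = 0.5)
observer_params <- function(g_target = 1, g_distractor = 0.3, bias_b = 0,
                            mod_depth_m = 0.4, pref_phase_rad = 0,
                            listen_mod_depth = 0.15, motor_sd_ms = 35,
                            motor_lag_ms = 20, motor_drift_sd_ms = 20,
                            motor_drift_rho = 0.8, miss_prob = 0.02) {
  obs <- list(
    g_target = g_target, g_distractor = g_distractor, bias_b = bias_b,
    mod_depth_m = mod_depth_m, pref_phase_rad = pref_phase_rad,
    listen_mod_depth = listen_mod_depth, motor_sd_ms = motor_sd_ms,
    motor_lag_ms = motor_lag_ms, motor_drift_sd_ms = motor_drift_sd_ms,
    motor_drift_rho = motor_drift_rho, miss_prob = miss_prob
  )
  if (!all(vapply(obs, function(x) is.numeric(x) && length(x) == 1 &&
                    is.finite(x), logical(1)))) {
    abort("All observer parameters must be single finite numbers.",
          class = "tapgain_invalid_argument")
  }
  if (mod_depth_m < 0 || mod_depth_m > 1 ||
      listen_mod_depth < 0 || listen_mod_depth > 1) {
    abort("Modulation depths must lie in [0, 1].",
          class = "tapgain_invalid_argument")
  }
  if (miss_prob < 0 || miss_prob >= 1) {
    abort("`miss_prob` must lie in [0, 1).",
          class = "tapgain_invalid_argument")
  }
  if (motor_sd_ms < 0 || motor_drift_sd_ms < 0 ||
      motor_drift_rho < 0 || motor_drift_rho >= 1) {
    abort("Tap-timing parameters out of range.",
          class = "tapgain_invalid_argument")
  }
  structure(obs, class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat("<observer_params>\n")
  cat(sprintf("  gains: target %.3f, distractor %.3f, bias %.3f\n",
              x$g_target, x$g_distractor, x$bias_b))
  cat(sprintf("  modulation: motor depth %.2f at phase %.2f rad, listen depth %.2f\n",
              x$mod_depth_m, x$pref_phase_rad, x$listen_mod_depth))
  cat(sprintf("  tapping: sd %.0f ms, lag %.0f ms, drift %.0f ms (rho %.2f), miss %.3f\n",
              x$motor_sd_ms, x$motor_lag_ms, x$motor_drift_sd_ms,
              x$motor_drift_rho, x$miss_prob))
  invisible(x)
}

check_observer <- function(obs) {
  if (!inherits(obs, "observer_params")) {
    abort("`obs` must be an `observer_params` object.",
          class = "tapgain_invalid_argument")
  }
  obs
}

#' Draw a heterogeneous population of observers
#'
#' Per-participant parameters vary around the [observer_params()] defaults:
#' log-normal gains, uniform modulation depths (motor depth always above the
#' covert listen depth on average), and individual tapping noise, lag and
#' wander. Used for group-level simulations.
#'
#' @param n Number of participants.
#' @param seed Optional integer seed.
#' @param mod_depth_range,listen_mod_range Uniform ranges for the two
#'   modulation depths.
#' @param g_distractor_mean,g_distractor_sd Normal law of the distractor
#'   gain across participants (truncated just above zero).
#' @param null_effect If `TRUE`, both modulation depths are set to zero so
#'   the motor and listen conditions share identical gain structure (a
#'   population in which every condition contrast is null).
#' @return A tibble, one row per participant, with a `participant` id and
#'   one column per observer parameter.
#' @export
observer_population <- function(n, seed = NULL,
                                mod_depth_range = c(0.25, 0.6),
                                listen_mod_range = c(0.05, 0.25),
                                g_distractor_mean = 0.3,
                                g_distractor_sd = 0.12,
                                null_effect = FALSE) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, observer_population(
      n, NULL, mod_depth_range, listen_mod_range, g_distractor_mean,
      g_distractor_sd, null_effect
    )))
  }
  pop <- tibble(
    participant = seq_len(n),
    g_target = stats::rlnorm(n, log(1), 0.25),
    g_distractor = pmax(rnorm(n, g_distractor_mean, g_distractor_sd), 0.02),
    bias_b = rnorm(n, 0, 0.1),
    mod_depth_m = runif(n, mod_depth_range[1], mod_depth_range[2]),
    pref_phase_rad = 0,
    listen_mod_depth = runif(n, listen_mod_range[1], listen_mod_range[2]),
    motor_sd_ms = runif(n, 25, 50),
    motor_lag_ms = runif(n, 5, 35),
    motor_drift_sd_ms = runif(n, 10, 30),
    motor_drift_rho = 0.8,
    miss_prob = runif(n, 0, 0.02)
  )
  if (null_effect) {
    pop$mod_depth_m <- 0
    pop$listen_mod_depth <- 0
  }
  pop
}

#' Turn one row of an observer population into observer parameters
#'
#' @param row A one-row data frame with observer-parameter columns, e.g. a
#'   row of [observer_population()].
#' @return An `observer_params` object.
#' @export
as_observer_params <- function(row) {
  row <- as.list(row)
  keep <- intersect(names(row), names(formals(observer_params)))
  do.call(observer_params, row[keep])
}

#' Simulate tap trains for motor-condition trials
#'
#' One intended press per theoretical beat from the second reference beat to
#' the end of the sequence. Press times are beat + constant lag + slow AR(1)
#' wander + white noise; each press is independently unrecorded ("missed")
#' with probability `miss_prob`. Taps are anchored to the beat, never to the
#' jittered tone onsets.
#'
#' @param tones Tone tibble of motor-condition trials.
#' @param obs An [observer_params()] object.
#' @param seed Optional integer seed.
#' @return A tibble with columns `trial_id`, `tap_index` (beat index, 1 =
#'   second reference beat), `tap_time_ms`, `missed`.
#' @export
simulate_taps <- function(tones, obs, seed = NULL) {
  obs <- check_observer(obs)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_taps(tones, obs, NULL)))
  }
  trials <- trial_summary(tones)
  if (any(trials$condition != "motor")) {
    abort("Tap trains exist only in the motor condition.",
          class = "tapgain_invalid_argument")
  }
  n <- nrow(trials)
  k <- N_BEATS - 1L
  if (n == 0) {
    return(tibble(trial_id = integer(0), tap_index = integer(0),
                  tap_time_ms = numeric(0), missed = logical(0)))
  }
  beats <- BEAT_PERIOD_MS * seq_len(k)
  drift <- matrix(0, nrow = k, ncol = n)
  rho <- obs$motor_drift_rho
  step <- obs$motor_drift_sd_ms
  stat_sd <- if (step > 0) step / sqrt(1 - rho^2) else 0
  drift[1, ] <- rnorm(n, 0, stat_sd)
  if (k > 1 && step > 0) {
    for (i in 2:k) {
      drift[i, ] <- rho * drift[i - 1, ] + rnorm(n, 0, step)
    }
  }
  tap <- beats + obs$motor_lag_ms + drift +
    matrix(rnorm(k * n, 0, obs$motor_sd_ms), nrow = k)
  tibble(
    trial_id = rep(trials$trial_id, each = k),
    tap_index = rep(seq_len(k), times = n),
    tap_time_ms = as.numeric(tap),
    missed = runif(k * n) < obs$miss_prob
  )
}

#' Simulate choices from the rhythmic-gain observer
#'
#' Computes each tone's phase in the relevant gain cycle -- the tap train in
#' the motor condition (including intended-but-missed presses: the motor
#' rhythm continues through a recording miss) or the covert beat-locked cycle
#' in the listen condition -- applies the multiplicative cosine gain, and
#' draws one Bernoulli choice per trial from the probit decision rule. The
#' covert cycle is anchored to the target stream, so in exp3 (targets in
#' antiphase with the beat) it peaks at the off-beat phase; the motor-locked
#' modulation is synergistic and switches off in exp3, where the tapped beat
#' is in phase opposition to the attended stream.
#'
#' @param tones Tone tibble (any mix of conditions).
#' @param taps Tap tibble from [simulate_taps()]; required if any trial is in
#'   the motor condition.
#' @param obs An [observer_params()] object.
#' @param seed Optional integer seed.
#' @return A tibble with one row per trial: `trial_id`, `choice`
#'   (`"high"`/`"low"`), `p_high_true`, `correct`.
#' @export
simulate_choices <- function(tones, taps = NULL, obs, seed = NULL) {
  obs <- check_observer(obs)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_choices(tones, taps, obs, NULL)))
  }
  trials <- arrange(trial_summary(tones), .data$trial_id)
  if (nrow(trials) == 0) {
    return(tibble(trial_id = integer(0), choice = character(0),
                  p_high_true = numeric(0), correct = logical(0)))
  }
  td <- filter(tones, .data$role %in% c("target", "distractor"))
  is_motor <- td$condition == "motor"
  phi <- numeric(nrow(td))
  m_eff <- numeric(nrow(td))
  if (any(is_motor)) {
    if (is.null(taps)) {
      abort("Motor-condition trials need a tap train (`taps` is missing).",
            class = "tapgain_invalid_argument")
    }
    ph <- assign_phase(td[is_motor, , drop = FALSE], taps = taps,
                       source = "motor")
    phi[is_motor] <- ph$ssi_rad
    m_eff[is_motor] <- ifelse(td$experiment[is_motor] == "exp3",
                              0, obs$mod_depth_m)
  }
  if (any(!is_motor)) {
    anchor <- ifelse(td$experiment == "exp3", pi, 0)
    beat_phi <- 2 * pi * (td$onset_ms %% BEAT_PERIOD_MS) / BEAT_PERIOD_MS
    phi[!is_motor] <- (beat_phi - anchor)[!is_motor]
    m_eff[!is_motor] <- obs$listen_mod_depth
  }
  g_role <- ifelse(td$role == "target", obs$g_target, obs$g_distractor)
  g_k <- g_role * (1 + m_eff * cos(phi - obs$pref_phase_rad))
  dv <- rowsum(g_k * td$f_log2, group = td$trial_id, reorder = TRUE)
  dv <- dv[match(trials$trial_id, as.numeric(rownames(dv))), 1]
  p_high <- pnorm(dv + obs$bias_b)
  choice_high <- rbinom(nrow(trials), 1, p_high) == 1
  tibble(
    trial_id = trials$trial_id,
    choice = ifelse(choice_high, "high", "low"),
    p_high_true = unname(p_high),
    correct = choice_high == (trials$f_tar_mean_log2 > 0)
  )
}

#' Simulate the choice on a single trial
#'
#' @param trial Tone tibble of one trial.
#' @param trace Tap tibble for that trial (required iff motor condition).
#' @param obs An [observer_params()] object.
#' @param seed Optional integer seed.
#' @return A one-row choice tibble, as [simulate_choices()].
#' @export
simulate_choice <- function(trial, trace = NULL, obs, seed = NULL) {
  cond <- unique(trial$condition)
  if (length(cond) != 1) {
    abort("`trial` must contain a single trial.",
          class = "tapgain_invalid_argument")
  }
  if (cond == "motor" && is.null(trace)) {
    abort("Motor-condition trial needs a tap trace.",
          class = "tapgain_invalid_argument")
  }
  simulate_choices(trial, taps = trace, obs = obs, seed = seed)
}

#' Adaptive weighted up-down staircase on the target-mean offset
#'
#' Runs listen-condition trials while adapting the magnitude of the target
#' mean-frequency offset: one step down after a correct response, `step_ratio`
#' steps up after an error. With the default 3:1 ratio the procedure
#' converges where `P(correct) = step_ratio / (step_ratio + 1) = 75%`. The
#' returned level is the mean offset over all reversals after discarding the
#' first `discard_reversals` (the approach phase); with a fixed small step
#' this pools the whole stationary stretch of the run, which carries far
#' less random-walk variance than a handful of final reversals.
#'
#' @param obs An [observer_params()] object.
#' @param experiment Experiment layout to titrate on.
#' @param n_trials Staircase length.
#' @param delta_init Starting offset (log2 units).
#' @param step_down Down-step size (log2 units).
#' @param step_ratio Up-step as a multiple of `step_down`.
#' @param delta_max Offset at which the staircase is declared divergent.
#' @param discard_reversals Reversals discarded as the approach phase; at
#'   least 8 reversals must remain after discarding.
#' @param sigma_f Per-tone frequency s.d.
#' @param seed Optional integer seed.
#' @return An object of class `staircase_result`: a list with `delta` (the
#'   converged offset), `reversals`, `trace` (per-trial tibble) and
#'   `n_trials`. Signals a `tapgain_staircase_error` (with the trace
#'   attached) if the staircase diverges or yields too few reversals.
#' @export
run_staircase <- function(obs, experiment = "exp1", n_trials = 400,
                          delta_init = 0.15, step_down = 0.004,
                          step_ratio = 3, delta_max = 1,
                          discard_reversals = 10, sigma_f = 0.2,
                          seed = NULL) {
  obs <- check_observer(obs)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, run_staircase(
      obs, experiment, n_trials, delta_init, step_down, step_ratio,
      delta_max, discard_reversals, sigma_f, NULL
    )))
  }
  delta <- delta_init
  last_dir <- 0L
  reversals <- numeric(0)
  deltas <- numeric(n_trials)
  corrects <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    tones <- generate_trials(1L, experiment, "listen", delta = delta,
                             sigma_f = sigma_f)
    ch <- simulate_choices(tones, NULL, obs)
    deltas[i] <- delta
    corrects[i] <- ch$correct
    dir <- if (ch$correct) -1L else 1L
    if (last_dir != 0L && dir != last_dir) {
      reversals <- c(reversals, delta)
    }
    last_dir <- dir
    delta <- delta + if (ch$correct) -step_down else step_ratio * step_down
    delta <- max(delta, 1e-4)
    if (delta >= delta_max) {
      abort(
        "Staircase diverged: the offset reached its ceiling, the observer's accuracy does not increase with the stimulus level.",
        class = "tapgain_staircase_error",
        trace = tibble(trial = seq_len(i), delta = deltas[seq_len(i)],
                       correct = corrects[seq_len(i)])
      )
    }
  }
  trace <- tibble(trial = seq_len(n_trials), delta = deltas,
                  correct = corrects)
  if (length(reversals) < discard_reversals + 8) {
    abort(
      sprintf("Staircase did not converge: only %d reversals within the trial budget.",
              length(reversals)),
      class = "tapgain_staircase_error", trace = trace
    )
  }
  structure(
    list(delta = mean(reversals[-seq_len(discard_reversals)]),
         reversals = reversals, trace = trace, n_trials = n_trials),
    class = "staircase_result"
  )
}

#' @export
print.staircase_result <- function(x, ...) {
  cat(sprintf("<staircase_result> converged offset %.4f log2 units (%d reversals, %d trials)\n",
              x$delta, length(x$reversals), x$n_trials))
  invisible(x)
}

#' Simulate a complete dataset for one observer
#'
#' Generates trials, tap trains and choices for every cell of the design:
#' listen and motor conditions (exp1/exp3) crossed with the four rhythmicity
#' regimes in exp2.
#'
#' @param obs An [observer_params()] object.
#' @param experiment Experiment layout.
#' @param n_trials_per_condition Trials per design cell.
#' @param delta Magnitude of the target-mean offset (log2 units), e.g. a
#'   staircase-converged level.
#' @param sigma_f Per-tone frequency s.d.
#' @param seed Optional integer seed; the whole dataset is reproducible.
#' @return A list of tibbles: `trials`, `tones`, `taps`, `choices`.
#' @export
simulate_dataset <- function(obs, experiment = "exp1",
                             n_trials_per_condition = 210, delta = 0.1,
                             sigma_f = 0.2, seed = NULL) {
  obs <- check_observer(obs)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_dataset(
      obs, experiment, n_trials_per_condition, delta, sigma_f, NULL
    )))
  }
  regimes <- if (experiment == "exp2") c("TD", "Td", "tD", "td") else "td"
  tones_all <- list()
  taps_all <- list()
  choices_all <- list()
  id0 <- 1L
  for (cond in c("listen", "motor")) {
    for (jc in regimes) {
      tones <- generate_trials(n_trials_per_condition, experiment, cond,
                               jitter_condition = jc, delta = delta,
                               sigma_f = sigma_f, trial_id_start = id0)
      id0 <- id0 + as.integer(n_trials_per_condition)
      taps <- NULL
      if (cond == "motor" && n_trials_per_condition > 0) {
        taps <- simulate_taps(tones, obs)
      }
      choices_all[[length(choices_all) + 1L]] <-
        simulate_choices(tones, taps, obs)
      tones_all[[length(tones_all) + 1L]] <- tones
      if (!is.null(taps)) taps_all[[length(taps_all) + 1L]] <- taps
    }
  }
  tones <- bind_rows(tones_all)
  taps <- if (length(taps_all) > 0) {
    bind_rows(taps_all)
  } else {
    tibble(trial_id = integer(0), tap_index = integer(0),
           tap_time_ms = numeric(0), missed = logical(0))
  }
  list(
    trials = trial_summary(tones),
    tones = tones,
    taps = taps,
    choices = bind_rows(choices_all)
  )
}
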