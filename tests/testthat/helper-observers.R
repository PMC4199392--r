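# Observers reused across tests. The "plain" observer has no gain
# modulation and noiseless bookkeeping where convenient; the "modulated"
# observer has tap-locked gain with zero lag so fitted phases are directly
# comparable to the generative preferred phase.

plain_observer <- function(...) {
  observer_params(g_target = 1, g_distractor = 0, bias_b = 0,
                  mod_depth_m = 0, listen_mod_depth = 0, miss_prob = 0, ...)
}

# Deep tap-locked modulation, zero lag, offset near the 75% point: the
# regime in which the interaction coefficients are well identified at a few
# thousand trials (probit information peaks near threshold).
modulated_observer <- function(...) {
  observer_params(g_target = 1.5, g_distractor = 0.45, bias_b = 0,
                  mod_depth_m = 0.8, listen_mod_depth = 0.15,
                  motor_lag_ms = 0, ...)
}

# Full analysis-side tap processing: observed taps -> complete corrected
# train.
process_taps <- function(taps) {
  observed <- dplyr::filter(taps, !missed)
  correct_delay(suppressMessages(interpolate_missing(observed)))
}

# Simulate one motor-condition dataset and return everything needed for a
# phase-resolved fit.
simulate_motor_data <- function(obs, n_trials, experiment = "exp1",
                                delta = 0.04, seed = 1) {
  withr::with_seed(seed, {
    tones <- generate_trials(n_trials, experiment, "motor", delta = delta)
    taps <- simulate_taps(tones, obs)
    choices <- simulate_choices(tones, taps, obs)
    phases <- assign_phase(tones, taps = process_taps(taps),
                           source = "motor")
    list(tones = tones, taps = taps, choices = choices, phases = phases)
  })
}
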