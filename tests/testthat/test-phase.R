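toy_taps <- function(times, trial_id = 1L) {
  tibble::tibble(trial_id = trial_id, tap_index = seq_along(times),
                 tap_time_ms = times)
}

test_that("delay correction removes exactly the constant lag", {
  beats <- make_reference_beat()
  taps <- toy_taps(beats[2:13] + 30)
  out <- correct_delay(taps)
  expect_equal(out$delay_offset_ms[1], 30)
  expect_equal(out$tap_time_ms, beats[2:13])

  out0 <- correct_delay(toy_taps(beats[2:13]))
  expect_equal(out0$delay_offset_ms[1], 0)

  # lag + noise: residual mean delay is zero by construction
  noisy <- withr::with_seed(1, toy_taps(beats[2:13] + 42 + rnorm(12, 0, 20)))
  outn <- correct_delay(noisy)
  expect_equal(outn$delay_offset_ms[1], 42, tolerance = 20)
  i <- round(outn$tap_time_ms / 667)
  expect_equal(mean(outn$tap_time_ms - 667 * i), 0, tolerance = 1e-9)

  expect_error(correct_delay(toy_taps(beats[2:5])),
               class = "tapgain_insufficient_data")
})

test_that("missing taps are filled on the line between their neighbours", {
  t1 <- interpolate_missing(toy_taps(c(0, 1334)))
  expect_equal(t1$tap_time_ms, c(0, 667, 1334))
  expect_equal(t1$interpolated, c(FALSE, TRUE, FALSE))

  t2 <- interpolate_missing(toy_taps(c(0, 1400)))
  expect_equal(t2$tap_time_ms[2], 700)

  full <- toy_taps(c(0, 660, 1340))
  expect_identical(interpolate_missing(full)$tap_time_ms, full$tap_time_ms)

  # consecutive misses lie on the connecting line (and are reported)
  expect_message(
    t3 <- interpolate_missing(toy_taps(c(0, 3 * 667))),
    "consecutive"
  )
  expect_equal(t3$tap_time_ms, 667 * (0:3))

  # an expected span extrapolates boundary taps from the beat period
  t4 <- interpolate_missing(toy_taps(c(667, 1334)), expected_indices = 1:3)
  expect_equal(t4$tap_time_ms, c(667, 1334, 2001))
  expect_true(t4$interpolated[3])
})

test_that("the simultaneity index is the tone's phase in the tap cycle", {
  tones <- generate_trials(1, "exp1", "motor", seed = 2)
  taps <- toy_taps(make_reference_beat()[2:13])
  ph <- assign_phase(tones, taps = taps, source = "motor")
  expect_equal(nrow(ph), 16)
  expect_true(all(ph$ssi_rad >= 0 & ph$ssi_rad < 2 * pi))

  # hand-built cases: at a tap, midway, and at 500 of a 667 cycle
  toy_tone <- function(onset) {
    tibble::tibble(trial_id = 1L, role = "target", index_in_role = 1L,
                   onset_ms = onset)
  }
  two_taps <- toy_taps(c(0, 667))
  expect_equal(assign_phase(toy_tone(0), two_taps, source = "motor")$ssi_rad, 0)
  expect_equal(assign_phase(toy_tone(667), two_taps,
                            source = "motor")$ssi_rad, 0)
  expect_equal(assign_phase(toy_tone(333.5), two_taps,
                            source = "motor")$ssi_rad, pi)
  expect_equal(assign_phase(toy_tone(500), two_taps,
                            source = "motor")$ssi_rad, 2 * pi * 500 / 667)

  # outside the tap span: beat-period extrapolation, flagged
  out <- assign_phase(toy_tone(667 + 500), two_taps, source = "motor")
  expect_true(out$boundary)
  expect_equal(out$ssi_rad, 2 * pi * 500 / 667)

  # nonmotor source uses the theoretical beat grid
  nm <- assign_phase(toy_tone(667), beat_times = make_reference_beat(),
                     source = "nonmotor")
  expect_equal(nm$ssi_rad, 0)
  expect_false(nm$boundary)
})

test_that("phase assignment is invariant to joint time translation", {
  obs <- modulated_observer()
  tones <- generate_trials(20, "exp1", "motor", seed = 3)
  taps <- simulate_taps(tones, obs, seed = 4)
  ph1 <- assign_phase(tones, taps = taps, source = "motor")
  shifted_tones <- dplyr::mutate(tones, onset_ms = onset_ms + 123.4)
  shifted_taps <- dplyr::mutate(taps, tap_time_ms = tap_time_ms + 123.4)
  ph2 <- assign_phase(shifted_tones, taps = shifted_taps, source = "motor")
  expect_equal(ph1$ssi_rad, ph2$ssi_rad, tolerance = 1e-9)
})

test_that("modulation fitting recovers the tap-locked gain cycle", {
  obs <- modulated_observer()
  dat <- simulate_motor_data(obs, 4000, seed = 5)
  mf <- fit_modulated_probit(dat$tones, dat$choices, dat$phases,
                             include_sine = TRUE)
  # generative values: w = g * m per role, preferred phase 0
  expect_lt(abs(mf$mod_strength["target"] - 1.5 * 0.8), 0.4)
  expect_lt(abs(mf$mod_strength["distractor"] - 0.45 * 0.8), 0.3)
  expect_lt(min(abs(c(mf$pref_phase_rad["target"],
                      2 * pi - mf$pref_phase_rad["target"]))), 0.3)
  expect_gte(mf$loglik_mod, mf$loglik_base)
  # main-effect gains are demodulated: close to g, not g * (1 + m cos)
  expect_lt(abs(pool_gains(mf)["g_target_pooled"] - 1.5), 0.3)

  ve <- variability_explained(fit_probit(build_design(dat$tones,
                                                      dat$choices)), mf)
  expect_gt(ve$deviance_improvement, 10)
  expect_gt(ve$delta_mcfadden_r2, 0)
})

test_that("without modulation the cosine coefficients and octile contrast vanish", {
  obs <- observer_params(mod_depth_m = 0, listen_mod_depth = 0,
                         g_target = 1, g_distractor = 0.3)
  dat <- simulate_motor_data(obs, 3000, seed = 6)
  mf <- fit_modulated_probit(dat$tones, dat$choices, dat$phases)
  expect_lt(abs(mf$w_cos["target"]), 3 * mf$se["cosf_tar"])
  expect_lt(abs(mf$w_cos["distractor"]), 3 * mf$se["cosf_dis"])

  base <- fit_probit(build_design(dat$tones, dat$choices))
  ve <- variability_explained(base, mf)
  expect_lt(ve$deviance_improvement, 9.5)

  prof <- suppressMessages(octile_profile(dat$tones, dat$choices,
                                          dat$phases))
  expect_equal(nrow(prof), 64)
  ctr <- octile_contrast(prof)
  expect_true(all(abs(ctr$difference) < 3 * ctr$se_difference))
})

test_that("modulated observers show the synchronous > asynchronous gain profile", {
  obs <- modulated_observer()
  dat <- simulate_motor_data(obs, 4000, seed = 7)
  prof <- suppressMessages(octile_profile(dat$tones, dat$choices,
                                          dat$phases))
  expect_equal(nrow(prof), 64)
  ctr <- octile_contrast(prof)
  expect_gt(ctr$difference[ctr$role == "target"], 0)
  expect_gt(ctr$difference[ctr$role == "distractor"], 0)
  # the synchronous extreme exceeds the pooled (phase-averaged) gain and
  # the asynchronous extreme falls below it
  pooled <- pool_gains(fit_gains(dat$tones, dat$choices))
  expect_gt(ctr$g_first[ctr$role == "target"],
            pooled["g_target_pooled"])
  expect_lt(ctr$g_last[ctr$role == "target"], pooled["g_target_pooled"])
})

test_that("the preferred phase is recovered across the cycle", {
  for (phase in c(0, pi / 2, pi, 3 * pi / 2)) {
    obs <- modulated_observer(pref_phase_rad = phase)
    dat <- simulate_motor_data(obs, 4000, seed = 8 + round(10 * phase))
    mf <- fit_modulated_probit(dat$tones, dat$choices, dat$phases,
                               include_sine = TRUE)
    err <- abs((mf$pref_phase_rad["target"] - phase + pi) %% (2 * pi) - pi)
    expect_lt(err, 0.3)
  }
})

test_that("nested-fit bookkeeping rejects mismatched inputs", {
  obs <- modulated_observer()
  dat <- simulate_motor_data(obs, 300, seed = 9)
  other <- simulate_motor_data(obs, 300, seed = 10)
  base_other <- fit_probit(build_design(other$tones, other$choices))
  mf <- fit_modulated_probit(dat$tones, dat$choices, dat$phases)
  expect_error(variability_explained(base_other, mf),
               class = "tapgain_invalid_argument")
  expect_error(variability_explained(mf, mf),
               class = "tapgain_invalid_argument")
})
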