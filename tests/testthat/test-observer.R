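test_that("tap trains are beat-locked with the prescribed noise structure", {
  obs0 <- observer_params(motor_sd_ms = 0, motor_lag_ms = 0,
                          motor_drift_sd_ms = 0, miss_prob = 0)
  tones <- generate_trials(3, "exp1", "motor", seed = 1)
  taps <- simulate_taps(tones, obs0, seed = 2)
  beats <- make_reference_beat()
  expect_equal(unique(taps$tap_time_ms[taps$tap_index == 1]), beats[2])
  expect_equal(taps$tap_time_ms[taps$trial_id == 1], beats[-1])
  expect_true(all(!taps$missed))

  # white-noise-only taps: per-tap deviation s.d. matches the generator
  obs_n <- observer_params(motor_sd_ms = 30, motor_lag_ms = 0,
                           motor_drift_sd_ms = 0, miss_prob = 0)
  tones_n <- generate_trials(500, "exp1", "motor", seed = 3)
  taps_n <- simulate_taps(tones_n, obs_n, seed = 4)
  dev <- taps_n$tap_time_ms - beats[taps_n$tap_index + 1]
  expect_equal(sd(dev), 30, tolerance = 0.05 * 30)

  # miss rate matches its probability over many intended presses
  obs_m <- observer_params(miss_prob = 0.02)
  taps_m <- simulate_taps(generate_trials(1000, "exp1", "motor", seed = 5),
                          obs_m, seed = 6)
  expect_lt(abs(mean(taps_m$missed) - 0.02), 0.006)

  expect_error(simulate_taps(generate_trials(2, "exp1", "listen", seed = 7),
                             obs0),
               class = "tapgain_invalid_argument")
})

test_that("choice probabilities follow the probit gain model in closed form", {
  tones <- generate_trials(50, "exp1", "listen", delta = 0.1, seed = 8)
  # zero gains and bias: exactly chance
  obs00 <- observer_params(g_target = 0, g_distractor = 0, bias_b = 0,
                           mod_depth_m = 0, listen_mod_depth = 0)
  ch <- simulate_choices(tones, NULL, obs00, seed = 9)
  expect_true(all(ch$p_high_true == 0.5))

  # unit target gain, no modulation: p = pnorm(sum of target frequencies)
  ch1 <- simulate_choices(tones, NULL, plain_observer(), seed = 10)
  f_sum <- tones |>
    dplyr::filter(role == "target") |>
    dplyr::group_by(trial_id) |>
    dplyr::summarise(s = sum(f_log2), .groups = "drop")
  expect_equal(ch1$p_high_true, pnorm(f_sum$s), tolerance = 1e-12)
  expect_equal(ch1$correct, (ch1$choice == "high") ==
                 (dplyr::distinct(tones, trial_id, f_tar_mean_log2)$f_tar_mean_log2 > 0))

  # modulation off: choice probabilities ignore the tap train entirely
  tones_m <- generate_trials(50, "exp1", "motor", delta = 0.1, seed = 11)
  obs_flat <- observer_params(mod_depth_m = 0, listen_mod_depth = 0)
  taps_a <- simulate_taps(tones_m, obs_flat, seed = 12)
  taps_b <- simulate_taps(tones_m, obs_flat, seed = 13)
  pa <- simulate_choices(tones_m, taps_a, obs_flat, seed = 14)$p_high_true
  pb <- simulate_choices(tones_m, taps_b, obs_flat, seed = 14)$p_high_true
  expect_equal(pa, pb, tolerance = 1e-12)

  expect_error(simulate_choice(tones_m[tones_m$trial_id == 1, ], NULL,
                               obs_flat),
               class = "tapgain_invalid_argument")
})

test_that("without modulation, listen and motor conditions are exchangeable", {
  obs <- observer_params(mod_depth_m = 0, listen_mod_depth = 0)
  tones_l <- generate_trials(100, "exp1", "listen", seed = 15)
  tones_m <- dplyr::mutate(tones_l, condition = "motor")
  taps <- simulate_taps(tones_m, obs, seed = 16)
  ch_l <- simulate_choices(tones_l, NULL, obs, seed = 17)
  ch_m <- simulate_choices(tones_m, taps, obs, seed = 17)
  expect_identical(ch_l, ch_m)
})

test_that("accuracy is non-decreasing in the target-mean offset", {
  obs <- observer_params()
  acc <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.4), function(d) {
    tones <- generate_trials(1500, "exp1", "listen", delta = d,
                             seed = 100 + round(1000 * d))
    mean(simulate_choices(tones, NULL, obs,
                          seed = 200 + round(1000 * d))$correct)
  }, numeric(1))
  expect_true(all(diff(acc) > -0.015))
  expect_gt(acc[5], 0.95)
})

test_that("the staircase inverts the psychometric function at 75%", {
  # noise-free psychometric: accuracy = pnorm(8 * delta), so the 75% point
  # is qnorm(0.75) / 8
  sc <- run_staircase(plain_observer(), n_trials = 800, seed = 21)
  expect_equal(sc$delta, qnorm(0.75) / 8, tolerance = 0.1)
  expect_gt(length(sc$reversals), 18)

  # an observer at chance never converges
  flat <- observer_params(g_target = 0, g_distractor = 0, mod_depth_m = 0,
                          listen_mod_depth = 0)
  err <- tryCatch(run_staircase(flat, seed = 22), error = identity)
  expect_s3_class(err, "tapgain_staircase_error")
  expect_s3_class(err$trace, "tbl_df")
})

test_that("dataset simulation is deterministic bookkeeping", {
  obs <- observer_params()
  ds <- simulate_dataset(obs, "exp1", n_trials_per_condition = 30,
                         seed = 23)
  expect_equal(nrow(ds$trials), 60)
  expect_equal(sum(ds$trials$condition == "motor"), 30)
  expect_setequal(unique(ds$taps$trial_id),
                  ds$trials$trial_id[ds$trials$condition == "motor"])
  expect_equal(nrow(ds$choices), 60)
  ds2 <- simulate_dataset(obs, "exp1", n_trials_per_condition = 30,
                          seed = 23)
  expect_identical(ds, ds2)

  ds0 <- simulate_dataset(obs, "exp1", n_trials_per_condition = 0, seed = 24)
  expect_equal(nrow(ds0$tones), 0)
  expect_equal(nrow(ds0$choices), 0)

  ds_e2 <- simulate_dataset(obs, "exp2", n_trials_per_condition = 5,
                            seed = 25)
  expect_equal(nrow(ds_e2$trials), 40)  # 2 conditions x 4 regimes x 5
  expect_setequal(unique(ds_e2$trials$jitter_condition),
                  c("TD", "Td", "tD", "td"))
})
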