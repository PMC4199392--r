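test_that("the design matrix has one column per tone position plus intercept", {
  obs <- plain_observer()
  tones <- generate_trials(60, "exp1", "listen", seed = 1)
  ch <- simulate_choices(tones, NULL, obs, seed = 2)
  d <- build_design(tones, ch)
  expect_equal(ncol(d$x), 17)
  expect_equal(colnames(d$x)[1], "(Intercept)")
  expect_equal(length(d$target_cols), 8)

  tones2 <- generate_trials(60, "exp2", "listen", seed = 3)
  ch2 <- simulate_choices(tones2, NULL, obs, seed = 4)
  expect_equal(ncol(build_design(tones2, ch2)$x), 18)

  # a trial whose tones all sit at f0 contributes an intercept-only row
  tones0 <- dplyr::mutate(tones, f_log2 = ifelse(trial_id == 5, 0, f_log2))
  d0 <- build_design(tones0, ch)
  expect_equal(unname(d0$x[d0$trial_id == 5, -1]), rep(0, 16))

  expect_error(build_design(tones, ch[-3, ]),
               class = "tapgain_data_integrity")
  expect_error(build_design(tones[-5, ], ch),
               class = "tapgain_data_integrity")
})

test_that("probit ML recovers generative gains and matches its own link", {
  obs <- plain_observer()
  tones <- generate_trials(2000, "exp1", "listen", delta = 0.1, seed = 5)
  ch <- simulate_choices(tones, NULL, obs, seed = 6)
  fit <- fit_gains(tones, ch)
  pooled <- pool_gains(fit)
  expect_equal(unname(pooled["g_target_pooled"]), 1, tolerance = 0.15)
  expect_equal(unname(pooled["g_distractor_pooled"]), 0, tolerance = 0.15)
  expect_lt(abs(fit$coefficients["(Intercept)"]), 0.1)
  expect_true(fit$converged)
  expect_false(fit$separation)
  expect_lte(fit$loglik, 0)
  # pooled gains are the means of the per-position gains
  expect_equal(unname(pooled["g_target_pooled"]),
               mean(fit$coefficients[fit$target_cols]))

  td <- tidy(fit)
  expect_equal(nrow(td), 17)
  expect_equal(sum(td$role == "target"), 8)
  expect_equal(glance(fit)$nobs, 2000)
})

test_that("fitting is invariant to tone row order", {
  obs <- plain_observer()
  tones <- generate_trials(300, "exp1", "listen", seed = 7)
  ch <- simulate_choices(tones, NULL, obs, seed = 8)
  fit1 <- fit_gains(tones, ch)
  perm <- withr::with_seed(9, tones[sample(nrow(tones)), ])
  fit2 <- fit_gains(perm, ch)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-10)
})

test_that("degenerate responses are flagged as separation, not silent divergence", {
  obs <- plain_observer()
  tones <- generate_trials(200, "exp1", "listen", seed = 10)
  ch <- simulate_choices(tones, NULL, obs, seed = 11)
  ch$choice <- "high"
  expect_warning(fit <- fit_gains(tones, ch), class = "tapgain_separation")
  expect_true(fit$separation)
  expect_false(fit$converged)
})

test_that("the fitted log-likelihood matches a direct-search oracle", {
  obs <- plain_observer()
  tones <- generate_trials(200, "exp1", "listen", delta = 0.1, seed = 12)
  ch <- simulate_choices(tones, NULL, obs, seed = 13)
  d <- build_design(tones, ch)
  fit <- fit_probit(d)
  oracle <- oracle_probit_maximum(d$x, d$y)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
  # the package's log-likelihood value is reproduced by the independent
  # hand-coded likelihood at the fitted coefficients
  expect_equal(fit$loglik,
               oracle_probit_loglik(fit$coefficients, d$x, d$y),
               tolerance = 1e-8)
})

test_that("gains separate from stimulus strength: doubling the offset leaves gains unchanged", {
  obs <- plain_observer()
  acc <- c(NA_real_, NA_real_)
  pooled <- c(NA_real_, NA_real_)
  for (i in 1:2) {
    d <- c(0.06, 0.12)[i]
    tones <- generate_trials(2000, "exp1", "listen", delta = d,
                             seed = 14)
    ch <- simulate_choices(tones, NULL, obs, seed = 15)
    acc[i] <- mean(ch$correct)
    pooled[i] <- pool_gains(fit_gains(tones, ch))["g_target_pooled"]
  }
  expect_gt(acc[2], acc[1] + 0.05)
  expect_equal(pooled[1], pooled[2], tolerance = 0.25)
  expect_equal(pooled, c(1, 1), tolerance = 0.2)
})

test_that("target influence grows with frequency distance, distractor influence stays flat", {
  obs <- plain_observer()
  tones <- generate_trials(4000, "exp1", "listen", delta = 0.08, seed = 16)
  ch <- simulate_choices(tones, NULL, obs, seed = 17)
  infl <- influence_by_distance(tones, ch, n_bins = 3)
  tar <- dplyr::filter(infl, role == "target")
  dis <- dplyr::filter(infl, role == "distractor")
  expect_true(all(diff(tar$influence) > 0))
  expect_true(all(abs(dis$influence) < 3 * dis$std.error))

  # single-bin reduction: one overall influence weight per role
  infl1 <- influence_by_distance(tones, ch, n_bins = 1)
  expect_equal(nrow(infl1), 2)
  expect_gt(infl1$influence[infl1$role == "target"], 0)
})

test_that("with no modulation, listen and motor gains agree across observers", {
  set.seed(18)
  pop <- observer_population(20, null_effect = TRUE)
  eff <- purrr::map_dbl(seq_len(20), function(i) {
    obs <- as_observer_params(pop[i, ])
    tones_l <- generate_trials(200, "exp1", "listen", delta = 0.1,
                               seed = 300 + i)
    tones_m <- generate_trials(200, "exp1", "motor", delta = 0.1,
                               seed = 600 + i, trial_id_start = 201L)
    taps <- simulate_taps(tones_m, obs, seed = 900 + i)
    g_l <- pool_gains(fit_gains(tones_l,
                                simulate_choices(tones_l, NULL, obs,
                                                 seed = 1200 + i)))
    g_m <- pool_gains(fit_gains(tones_m,
                                simulate_choices(tones_m, taps, obs,
                                                 seed = 1500 + i)))
    g_m["g_target_pooled"] - g_l["g_target_pooled"]
  })
  expect_gt(paired_t(eff, rep(0, 20))$p.value, 0.05)
})
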