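#' Remove the participant-constant tap recording delay
#'
#' Matches every tap to the nearest theoretical reference beat and subtracts
#' one constant offset (the trial-averaged tap-to-beat delay) from all tap
#' times, so that zero sensorimotor phase corresponds to zero lag. The
#' correction is constant within a participant; apply it to all of a
#' participant's taps at once.
#'
#' @param taps Tap tibble (`trial_id`, `tap_time_ms`, ...). Pass observed
#'   taps only.
#' @param beat_times Theoretical beat times in ms.
#' @param min_taps Minimum number of matched taps required.
#' @return `taps` with shifted `tap_time_ms` and a `delay_offset_ms` column
#'   recording the applied offset.
#' @export
correct_delay <- function(taps, beat_times = make_reference_beat(),
                          min_taps = 10) {
  validate_taps(taps)
  if (nrow(taps) < min_taps) {
    abort(sprintf("Only %d taps: too few to estimate the recording delay (need >= %d).",
                  nrow(taps), min_taps),
          class = "tapgain_insufficient_data")
  }
  bt <- sort(beat_times)
  i <- findInterval(taps$tap_time_ms, bt)
  lo <- bt[pmax(i, 1)]
  hi <- bt[pmin(i + 1, length(bt))]
  nearest <- ifelse(i == 0, hi,
                    ifelse(taps$tap_time_ms - lo <= hi - taps$tap_time_ms,
                           lo, hi))
  offset <- mean(taps$tap_time_ms - nearest)
  mutate(taps, tap_time_ms = .data$tap_time_ms - offset,
         delay_offset_ms = offset)
}

#' Interpolate missing taps
#'
#' Assigns each observed tap to its nearest beat index and fills absent
#' indices by linear interpolation between the flanking observed taps (for a
#' run of consecutive misses the interpolants lie on the connecting line).
#' A missing first or last tap is extrapolated from its neighbour using the
#' beat period and flagged.
#'
#' @param trace Observed tap tibble (`trial_id`, `tap_time_ms`).
#' @param period_ms Beat period, used to match taps to beat indices and for
#'   boundary extrapolation.
#' @param expected_indices Beat indices at which a tap is expected. By
#'   default the observed span of each trial (interior gaps only); pass the
#'   full design span to also extrapolate missing first/last taps from the
#'   beat period (such taps are flagged).
#' @return A complete tap tibble with columns `trial_id`, `tap_index`,
#'   `tap_time_ms`, `interpolated`.
#' @export
interpolate_missing <- function(trace, period_ms = BEAT_PERIOD_MS,
                                expected_indices = NULL) {
  validate_taps(trace)
  bi <- as.integer(round(trace$tap_time_ms / period_ms))
  # Successive taps must land on successive beats: where rounding collides
  # (a tap drifted past half a period), assign indices greedily in time
  # order within the trial.
  if (anyDuplicated(paste(trace$trial_id, bi))) {
    bad_ids <- unique(trace$trial_id[duplicated(paste(trace$trial_id, bi))])
    for (id in bad_ids) {
      sel <- which(trace$trial_id == id)
      sel <- sel[order(trace$tap_time_ms[sel])]
      b <- bi[sel]
      for (k in seq_along(b)[-1]) {
        b[k] <- max(b[k], b[k - 1] + 1L)
      }
      bi[sel] <- b
    }
  }
  df <- tibble(trial_id = trace$trial_id, tap_index = bi,
               tap_time_ms = trace$tap_time_ms, interpolated = FALSE)
  has_gap <- df |>
    group_by(.data$trial_id) |>
    summarise(gap = (if (is.null(expected_indices)) {
      max(.data$tap_index) - min(.data$tap_index) + 1L > n()
    } else {
      !all(expected_indices %in% .data$tap_index)
    }), .groups = "drop")
  complete_ids <- has_gap$trial_id[!has_gap$gap]
  done <- df[df$trial_id %in% complete_ids, ]
  todo <- df[!df$trial_id %in% complete_ids, ]
  if (nrow(todo) > 0) {
    filled <- lapply(split(todo, todo$trial_id), function(tr) {
      tr <- tr[order(tr$tap_index), ]
      expected <- if (is.null(expected_indices)) {
        seq(min(tr$tap_index), max(tr$tap_index))
      } else {
        expected_indices
      }
      miss <- setdiff(expected, tr$tap_index)
      runs <- split(miss, cumsum(c(1, diff(miss) != 1)))
      if (any(vapply(runs, length, integer(1)) > 1)) {
        inform(paste0("Trial ", tr$trial_id[1],
                      ": consecutive missing taps filled along the connecting line."))
      }
      t_new <- vapply(miss, function(i) {
        prev <- tr$tap_index[tr$tap_index < i]
        nxt <- tr$tap_index[tr$tap_index > i]
        if (length(prev) > 0 && length(nxt) > 0) {
          p <- max(prev); q <- min(nxt)
          tp <- tr$tap_time_ms[tr$tap_index == p]
          tq <- tr$tap_time_ms[tr$tap_index == q]
          tp + (tq - tp) * (i - p) / (q - p)
        } else if (length(nxt) > 0) {
          q <- min(nxt)
          tr$tap_time_ms[tr$tap_index == q] - period_ms * (q - i)
        } else {
          p <- max(prev)
          tr$tap_time_ms[tr$tap_index == p] + period_ms * (i - p)
        }
      }, numeric(1))
      bind_rows(tr, tibble(trial_id = tr$trial_id[1], tap_index = miss,
                           tap_time_ms = t_new, interpolated = TRUE))
    })
    todo <- bind_rows(filled)
  }
  arrange(bind_rows(done, todo), .data$trial_id, .data$tap_index)
}

# Phase of event times within the cycles spanned by an increasing tap grid:
# phi = 2*pi*(t - T_i)/(T_{i+1} - T_i) for T_i <= t <= T_{i+1}; outside the
# grid the phase is extrapolated with the beat period anchored at the
# nearest end tap (flagged as boundary). An event exactly at a tap gets 0.
phase_in_grid <- function(t, grid, period_ms) {
  i <- findInterval(t, grid)
  n <- length(grid)
  phi <- numeric(length(t))
  boundary <- logical(length(t))
  before <- i == 0
  at_end <- i == n
  interior <- !before & !at_end
  if (any(interior)) {
    ii <- i[interior]
    phi[interior] <- 2 * pi * (t[interior] - grid[ii]) /
      (grid[ii + 1] - grid[ii])
  }
  if (any(before)) {
    phi[before] <- 2 * pi * (((t[before] - grid[1]) %% period_ms) / period_ms)
    boundary[before] <- TRUE
  }
  if (any(at_end)) {
    phi[at_end] <- 2 * pi * (((t[at_end] - grid[n]) %% period_ms) / period_ms)
    boundary[at_end] <- t[at_end] > grid[n]
  }
  list(phi = phi %% (2 * pi), boundary = boundary)
}

#' Assign each tone its sensorimotor (or beat) phase
#'
#' The sensorimotor simultaneity index (SSI) treats the interval between two
#' successive motor acts as one cycle, with phase 0 at the act: a tone at
#' time `t` between taps `T_i < t <= T_{i+1}` gets
#' `SSI = 2*pi*(t - T_i)/(T_{i+1} - T_i)`. With `source = "nonmotor"` the
#' theoretical reference beats replace the taps (the control analysis).
#' Tones outside the tap span are extrapolated with the beat period and
#' flagged.
#'
#' @param tones Tone tibble; only targets and distractors are indexed.
#' @param taps Complete tap tibble (after [interpolate_missing()] /
#'   [correct_delay()]) covering every trial in `tones`; required for
#'   `source = "motor"`.
#' @param beat_times Beat times used when `source = "nonmotor"`.
#' @param source `"motor"` or `"nonmotor"`.
#' @param period_ms Cycle period used for boundary extrapolation.
#' @return A tibble aligned with the target/distractor rows of `tones`:
#'   `trial_id`, `role`, `index_in_role`, `onset_ms`, `ssi_rad` in
#'   `[0, 2*pi)`, `source`, `boundary`.
#' @export
assign_phase <- function(tones, taps = NULL, beat_times = NULL,
                         source = c("motor", "nonmotor"),
                         period_ms = BEAT_PERIOD_MS) {
  source <- match.arg(source)
  tt <- filter(tones, .data$role %in% c("target", "distractor"))
  if (source == "nonmotor") {
    if (is.null(beat_times)) beat_times <- make_reference_beat()
    ph <- phase_in_grid(tt$onset_ms, sort(beat_times), period_ms)
    return(tibble(trial_id = tt$trial_id, role = tt$role,
                  index_in_role = tt$index_in_role, onset_ms = tt$onset_ms,
                  ssi_rad = ph$phi, source = source,
                  boundary = ph$boundary))
  }
  if (is.null(taps)) {
    abort("`taps` is required for motor-source phase assignment.",
          class = "tapgain_invalid_argument")
  }
  lev <- sort(unique(taps$trial_id))
  code_tone <- match(tt$trial_id, lev)
  if (anyNA(code_tone)) {
    bad <- tt$trial_id[which(is.na(code_tone))][1]
    abort(paste0("No tap train for trial ", bad, "."),
          class = "tapgain_data_integrity")
  }
  ord <- order(match(taps$trial_id, lev), taps$tap_time_ms)
  code_tap <- match(taps$trial_id, lev)[ord]
  tap_t <- taps$tap_time_ms[ord]
  if (any(diff(tap_t)[diff(code_tap) == 0] <= 0)) {
    bad <- lev[code_tap[which(diff(tap_t) <= 0 & diff(code_tap) == 0)[1]]]
    abort(paste0("Tap times are not strictly increasing in trial ", bad, "."),
          class = "tapgain_data_integrity")
  }
  off <- 10 * max(abs(c(tap_t, tt$onset_ms)), period_ms)
  tap_g <- tap_t + (code_tap - 1) * off
  tone_g <- tt$onset_ms + (code_tone - 1) * off
  first <- match(seq_along(lev), code_tap)
  last <- cumsum(tabulate(code_tap, nbins = length(lev)))
  i <- findInterval(tone_g, tap_g)
  f_i <- first[code_tone]
  l_i <- last[code_tone]
  phi <- numeric(nrow(tt))
  boundary <- logical(nrow(tt))
  before <- i < f_i
  at_end <- !before & i >= l_i
  interior <- !before & !at_end
  if (any(interior)) {
    ii <- i[interior]
    phi[interior] <- 2 * pi * (tone_g[interior] - tap_g[ii]) /
      (tap_g[ii + 1] - tap_g[ii])
  }
  if (any(before)) {
    anchor <- tap_g[f_i[before]]
    phi[before] <- 2 * pi * (((tone_g[before] - anchor) %% period_ms) /
                               period_ms)
    boundary[before] <- TRUE
  }
  if (any(at_end)) {
    anchor <- tap_g[l_i[at_end]]
    phi[at_end] <- 2 * pi * (((tone_g[at_end] - anchor) %% period_ms) /
                               period_ms)
    boundary[at_end] <- tone_g[at_end] > anchor
  }
  tibble(trial_id = tt$trial_id, role = tt$role,
         index_in_role = tt$index_in_role, onset_ms = tt$onset_ms,
         ssi_rad = phi %% (2 * pi), source = source, boundary = boundary)
}

join_phases <- function(tones, phases) {
  td <- filter(tones, .data$role %in% c("target", "distractor"))
  td <- left_join(td,
                  select(phases, "trial_id", "role", "index_in_role",
                         "ssi_rad"),
                  by = c("trial_id", "role", "index_in_role"))
  if (anyNA(td$ssi_rad)) {
    bad <- td$trial_id[which(is.na(td$ssi_rad))][1]
    abort(paste0("No phase assigned for some tones of trial ", bad, "."),
          class = "tapgain_data_integrity")
  }
  td
}

#' Sliding-octile profile of sensory gain versus sensorimotor simultaneity
#'
#' Orders tones of each role by their simultaneity score (circular distance
#' of the SSI to phase 0, in `[0, pi]`) and estimates sensory gain inside 64
#' overlapping windows, each spanning one octile (12.5%) of the role's score
#' distribution, with centres stepped by 1/64 quantile. Each window fit is a
#' probit regression of choice on the in-window frequency sums of both
#' roles, with the out-of-window sums retained as nuisance regressors.
#'
#' @param tones,choices Tone and choice tibbles.
#' @param phases Phase tibble from [assign_phase()].
#' @param n_windows Number of sliding windows.
#' @param window_frac Fraction of the score distribution per window.
#' @param min_tones Minimum tones per role per window; narrower windows are
#'   widened symmetrically (and reported).
#' @return A tibble of class `octile_profile`: one row per window with the
#'   quantile range, per-role median simultaneity scores and fitted in-window
#'   gains with standard errors.
#' @export
octile_profile <- function(tones, choices, phases, n_windows = 64,
                           window_frac = 1 / 8, min_tones = 50) {
  td <- join_phases(tones, phases)
  trials <- sort(unique(td$trial_id))
  ch <- choices$choice[match(trials, choices$trial_id)]
  if (anyNA(ch)) {
    abort("Some trials have no recorded choice.",
          class = "tapgain_data_integrity")
  }
  y <- ch == "high"
  row <- match(td$trial_id, trials)
  s <- pmin(td$ssi_rad, 2 * pi - td$ssi_rad)
  is_tar <- td$role == "target"
  q <- numeric(nrow(td))
  q[is_tar] <- (rank(s[is_tar], ties.method = "first") - 0.5) / sum(is_tar)
  q[!is_tar] <- (rank(s[!is_tar], ties.method = "first") - 0.5) / sum(!is_tar)
  step <- (1 - window_frac) / (n_windows - 1)
  widened <- 0L
  res <- purrr::map_dfr(seq_len(n_windows), function(j) {
    lo <- (j - 1) * step
    hi <- lo + window_frac
    in_w <- q >= lo & q <= hi
    for (r in c(TRUE, FALSE)) {
      sel <- if (r) is_tar else !is_tar
      grow <- 0
      while (sum(in_w & sel) < min(min_tones, sum(sel)) && grow < 1) {
        grow <- grow + 0.5 / n_windows
        in_w <- in_w | (sel & q >= lo - grow & q <= hi + grow)
        widened <<- widened + 1L
      }
    }
    f <- td$f_log2
    x <- cbind(
      `(Intercept)` = 1,
      in_tar = as.numeric(rowsum(f * (in_w & is_tar), row)),
      out_tar = as.numeric(rowsum(f * (!in_w & is_tar), row)),
      in_dis = as.numeric(rowsum(f * (in_w & !is_tar), row)),
      out_dis = as.numeric(rowsum(f * (!in_w & !is_tar), row))
    )
    fit <- fit_binary_glm(x, y)
    tibble(
      window = j, q_lo = lo, q_hi = hi,
      s_target_mid = stats::median(s[in_w & is_tar]),
      s_distractor_mid = stats::median(s[in_w & !is_tar]),
      n_target = sum(in_w & is_tar), n_distractor = sum(in_w & !is_tar),
      g_target = unname(fit$coefficients["in_tar"]),
      g_distractor = unname(fit$coefficients["in_dis"]),
      se_target = unname(fit$se["in_tar"]),
      se_distractor = unname(fit$se["in_dis"])
    )
  })
  if (widened > 0) {
    inform(sprintf("%d window/role combinations were widened to reach %d tones.",
                   widened, min_tones))
  }
  class(res) <- c("octile_profile", class(res))
  res
}

#' First-versus-last octile gain contrast
#'
#' Difference between the gain in the most synchronous window and the most
#' asynchronous window of an [octile_profile()].
#'
#' @param profile An `octile_profile` tibble.
#' @return A tibble with one row per role: first- and last-window gains,
#'   their difference, and the standard error of the difference.
#' @export
octile_contrast <- function(profile) {
  a <- profile[1, ]
  z <- profile[nrow(profile), ]
  tibble(
    role = c("target", "distractor"),
    g_first = c(a$g_target, a$g_distractor),
    g_last = c(z$g_target, z$g_distractor),
    difference = c(a$g_target - z$g_target,
                   a$g_distractor - z$g_distractor),
    se_difference = sqrt(c(a$se_target^2 + z$se_target^2,
                           a$se_distractor^2 + z$se_distractor^2))
  )
}

#' Probit fit with sensorimotor gain-modulation terms
#'
#' Augments the per-position reverse-correlation design with per-role
#' interaction regressors `sum_k cos(SSI_k) * f_k` (and optionally the sine
#' counterparts) and refits by maximum likelihood. The cosine coefficient is
#' the gain-modulation strength locked to the motor act; with the sine terms
#' included, the preferred phase of each role is `atan2(w_sin, w_cos)` and
#' the modulation strength is the amplitude `sqrt(w_cos^2 + w_sin^2)`.
#'
#' @param tones,choices Tone and choice tibbles.
#' @param phases Phase tibble from [assign_phase()].
#' @param include_sine Add sine interaction terms (for preferred-phase
#'   estimation).
#' @param link `"probit"` or `"logit"`.
#' @return An object of class `modulation_fit` with per-role `w_cos`,
#'   `w_sin`, `mod_strength` and `pref_phase_rad`, the augmented-model and
#'   base-model log-likelihoods, and the full coefficient vector.
#' @export
fit_modulated_probit <- function(tones, choices, phases,
                                 include_sine = FALSE,
                                 link = c("probit", "logit")) {
  link <- match.arg(link)
  d <- build_design(tones, choices)
  td <- join_phases(tones, phases)
  is_tar <- td$role == "target"
  row <- match(td$trial_id, d$trial_id)
  if (anyNA(row)) {
    abort("Phase table covers trials absent from the design.",
          class = "tapgain_data_integrity")
  }
  add <- cbind(
    cosf_tar = as.numeric(rowsum(cos(td$ssi_rad) * td$f_log2 * is_tar, row)),
    cosf_dis = as.numeric(rowsum(cos(td$ssi_rad) * td$f_log2 * !is_tar, row))
  )
  if (include_sine) {
    add <- cbind(
      add,
      sinf_tar = as.numeric(rowsum(sin(td$ssi_rad) * td$f_log2 * is_tar, row)),
      sinf_dis = as.numeric(rowsum(sin(td$ssi_rad) * td$f_log2 * !is_tar, row))
    )
  }
  base <- fit_binary_glm(d$x, d$y, link = link)
  mod <- fit_binary_glm(cbind(d$x, add), d$y, link = link)
  beta <- mod$coefficients
  w_cos <- c(target = unname(beta["cosf_tar"]),
             distractor = unname(beta["cosf_dis"]))
  w_sin <- if (include_sine) {
    c(target = unname(beta["sinf_tar"]),
      distractor = unname(beta["sinf_dis"]))
  } else {
    c(target = 0, distractor = 0)
  }
  structure(
    list(
      coefficients = beta, se = mod$se,
      w_cos = w_cos, w_sin = w_sin,
      mod_strength = if (include_sine) sqrt(w_cos^2 + w_sin^2) else w_cos,
      pref_phase_rad = atan2(w_sin, w_cos) %% (2 * pi),
      loglik_base = base$loglik, loglik_mod = mod$loglik,
      loglik_null = mod$loglik_null, include_sine = include_sine,
      converged = mod$converged, separation = mod$separation,
      n = mod$n, link = link,
      target_cols = d$target_cols, distractor_cols = d$distractor_cols,
      base_terms = colnames(d$x)
    ),
    class = "modulation_fit"
  )
}

#' @export
print.modulation_fit <- function(x, ...) {
  cat(sprintf("<modulation_fit> %s, %d trials, logLik %.2f (base %.2f)\n",
              x$link, x$n, x$loglik_mod, x$loglik_base))
  cat(sprintf("  modulation: target %.3f (phase %.2f rad), distractor %.3f (phase %.2f rad)\n",
              x$mod_strength["target"], x$pref_phase_rad["target"],
              x$mod_strength["distractor"], x$pref_phase_rad["distractor"]))
  invisible(x)
}

#' @rdname tapgain-tidiers
#' @export
tidy.modulation_fit <- function(x, ...) {
  term <- names(x$coefficients)
  role <- dplyr::case_when(
    term %in% x$target_cols | grepl("f_tar$", term) ~ "target",
    term %in% x$distractor_cols | grepl("f_dis$", term) ~ "distractor",
    TRUE ~ "bias"
  )
  type <- dplyr::case_when(
    grepl("^cosf", term) ~ "cos_modulation",
    grepl("^sinf", term) ~ "sin_modulation",
    term == "(Intercept)" ~ "bias",
    TRUE ~ "gain"
  )
  tibble(term = term, role = role, type = type,
         estimate = unname(x$coefficients), std.error = unname(x$se))
}

#' @rdname tapgain-tidiers
#' @export
glance.modulation_fit <- function(x, ...) {
  tibble(logLik = x$loglik_mod, logLik_base = x$loglik_base,
         logLik_null = x$loglik_null, df = length(x$coefficients),
         nobs = x$n, link = x$link, include_sine = x$include_sine,
         converged = x$converged, separation = x$separation)
}

#' Behavioural variability explained by sensorimotor simultaneity
#'
#' Improvement of the phase-modulated fit over the base reverse-correlation
#' fit on the same trials: the likelihood-ratio deviance improvement
#' `2 * (logLik_mod - logLik_base)` (non-negative by nesting) and the change
#' in McFadden pseudo-R-squared.
#'
#' @param base A `gain_fit` fitted on the same data.
#' @param mod A `modulation_fit` whose base terms nest the `base` fit.
#' @return A one-row tibble: `deviance_improvement`, `delta_mcfadden_r2`.
#' @export
variability_explained <- function(base, mod) {
  if (!inherits(base, "gain_fit") || !inherits(mod, "modulation_fit")) {
    abort("`base` must be a gain_fit and `mod` a modulation_fit.",
          class = "tapgain_invalid_argument")
  }
  same_terms <- setequal(names(base$coefficients), mod$base_terms)
  if (!same_terms || base$n != mod$n ||
      abs(base$loglik_null - mod$loglik_null) > 1e-6) {
    abort("Fits are not nested on identical data.",
          class = "tapgain_invalid_argument")
  }
  dev <- max(0, 2 * (mod$loglik_mod - base$loglik))
  r2_base <- 1 - base$loglik / base$loglik_null
  r2_mod <- 1 - mod$loglik_mod / mod$loglik_null
  tibble(deviance_improvement = dev,
         delta_mcfadden_r2 = max(0, r2_mod - r2_base))
}
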