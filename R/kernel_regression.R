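#' Build the reverse-correlation design matrix
#'
#' One row per trial, one column per target position and per distractor
#' position (log2-frequency distance to the reference), plus an intercept.
#' The response is the binary "high" judgement.
#'
#' @param tones Tone tibble.
#' @param choices Choice tibble with `trial_id` and `choice`.
#' @return A list: `x` (matrix, intercept first), `y` (logical response),
#'   `trial_id`, `target_cols`, `distractor_cols`.
#' @export
build_design <- function(tones, choices) {
  td <- filter(tones, .data$role %in% c("target", "distractor"))
  if (nrow(td) == 0) {
    abort("No target or distractor tones in `tones`.",
          class = "tapgain_data_integrity")
  }
  trials <- sort(unique(td$trial_id))
  missing_choice <- setdiff(trials, choices$trial_id)
  if (length(missing_choice) > 0) {
    abort(paste0("No choice recorded for trial(s): ",
                 paste(utils::head(missing_choice, 5), collapse = ", ")),
          class = "tapgain_data_integrity")
  }
  ch <- choices$choice[match(trials, choices$trial_id)]
  if (!all(ch %in% c("high", "low"))) {
    abort("`choice` must be 'high' or 'low'.",
          class = "tapgain_data_integrity")
  }
  key <- paste0(ifelse(td$role == "target", "tar_", "dis_"), td$index_in_role)
  if (anyDuplicated(paste(td$trial_id, key))) {
    dup <- td$trial_id[duplicated(paste(td$trial_id, key))][1]
    abort(paste0("Duplicated tone (role, position) in trial ", dup, "."),
          class = "tapgain_data_integrity")
  }
  target_cols <- paste0("tar_", sort(unique(td$index_in_role[td$role == "target"])))
  distractor_cols <- paste0("dis_", sort(unique(td$index_in_role[td$role == "distractor"])))
  cols <- c(target_cols, distractor_cols)
  x <- matrix(NA_real_, length(trials), length(cols),
              dimnames = list(NULL, cols))
  x[cbind(match(td$trial_id, trials), match(key, cols))] <- td$f_log2
  if (anyNA(x)) {
    bad <- trials[which(rowSums(is.na(x)) > 0)][1]
    abort(paste0("Trial ", bad, " is missing tones for some positions."),
          class = "tapgain_data_integrity")
  }
  list(x = cbind(`(Intercept)` = 1, x), y = ch == "high", trial_id = trials,
       target_cols = target_cols, distractor_cols = distractor_cols)
}

# Binomial log-likelihood with clamped probabilities.
binom_loglik <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  sum(log(ifelse(y, mu, 1 - mu)))
}

# ML fit of a binary GLM on a prebuilt matrix. ridge > 0 adds a quadratic
# penalty on all non-intercept coefficients (penalized IRLS); the reported
# loglik is always unpenalized.
fit_binary_glm <- function(x, y, link = "probit", tol = 1e-6, ridge = 0) {
  fam <- binomial(link = link)
  p <- ncol(x)
  n <- length(y)
  sep_warn <- FALSE
  conv_warn <- FALSE
  if (ridge == 0) {
    fit <- withCallingHandlers(
      glm.fit(x, as.numeric(y), family = fam,
              control = glm.control(epsilon = 1e-10, maxit = 200)),
      warning = function(w) {
        msg <- conditionMessage(w)
        if (grepl("fitted probabilities numerically 0 or 1", msg)) {
          sep_warn <<- TRUE
        } else if (grepl("did not converge", msg)) {
          conv_warn <<- TRUE
        }
        invokeRestart("muffleWarning")
      }
    )
    beta <- fit$coefficients
    w_irls <- fit$weights
  } else {
    pen <- rep(2 * ridge, p)
    pen[colnames(x) == "(Intercept)"] <- 0
    beta <- rep(0, p)
    for (it in seq_len(200)) {
      eta <- drop(x %*% beta)
      mu <- fam$linkinv(eta)
      mu.eta <- fam$mu.eta(eta)
      vv <- pmax(mu * (1 - mu), 1e-10)
      w <- mu.eta^2 / vv
      z <- eta + (y - mu) / pmax(mu.eta, 1e-10)
      xw <- x * w
      beta_new <- tryCatch(
        solve(crossprod(x, xw) + diag(pen, p), crossprod(xw, z)),
        error = function(e) NULL
      )
      if (is.null(beta_new)) break
      delta <- max(abs(beta_new - beta))
      beta <- drop(beta_new)
      if (delta < 1e-10) break
    }
    names(beta) <- colnames(x)
    eta <- drop(x %*% beta)
    mu <- fam$linkinv(eta)
    w_irls <- fam$mu.eta(eta)^2 / pmax(mu * (1 - mu), 1e-10)
  }
  ok <- !is.na(beta)
  eta <- drop(x[, ok, drop = FALSE] %*% beta[ok])
  mu <- fam$linkinv(eta)
  # score of the unpenalized log-likelihood at the estimate
  resid_w <- (y - mu) * fam$mu.eta(eta) / pmax(mu * (1 - mu), 1e-10)
  score <- drop(crossprod(x[, ok, drop = FALSE], resid_w))
  info <- crossprod(x[, ok, drop = FALSE] * sqrt(pmax(w_irls, 0)))
  if (ridge > 0) {
    pen <- rep(2 * ridge, sum(ok))
    pen[colnames(x)[ok] == "(Intercept)"] <- 0
    info <- info + diag(pen, sum(ok))
  }
  se <- rep(NA_real_, p)
  names(se) <- colnames(x)
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (!is.null(cov)) se[ok] <- sqrt(pmax(diag(cov), 0))
  separation <- sep_warn || all(y) || !any(y) ||
    any(abs(beta[ok]) > 15)
  if (all(y) || !any(y)) {
    warn("All responses are identical: complete separation, estimates are unreliable.",
         class = "tapgain_separation")
  }
  converged <- !conv_warn && all(ok) &&
    sqrt(sum(score^2)) < tol * max(1, n) && !separation
  p_bar <- mean(y)
  ll_null <- if (p_bar <= 0 || p_bar >= 1) 0 else
    sum(log(ifelse(y, p_bar, 1 - p_bar)))
  list(coefficients = beta, se = se, loglik = binom_loglik(y, mu),
       loglik_null = ll_null, converged = converged,
       separation = separation, n = n, link = link, ridge = ridge)
}

#' Maximum-likelihood probit fit of per-position sensory gains
#'
#' Fits `P(high) = pnorm(b + sum_k g_k f_k)` by maximum likelihood on a
#' design built with [build_design()] (or any matrix/response pair). The
#' probit link is the default because the decision model is written with the
#' cumulative normal; a logit option is available.
#'
#' @param design A list from [build_design()], or a numeric matrix (with
#'   intercept column) in which case `responses` must be given.
#' @param responses Logical/0-1 response vector when `design` is a matrix.
#' @param link `"probit"` (default) or `"logit"`.
#' @param tol Convergence declared when the score norm is below `tol * n`.
#' @param ridge Optional quadratic penalty on non-intercept coefficients
#'   (default 0: plain maximum likelihood).
#' @return An object of class `gain_fit`.
#' @export
fit_probit <- function(design, responses = NULL,
                       link = c("probit", "logit"), tol = 1e-6, ridge = 0) {
  link <- match.arg(link)
  if (is.list(design) && !is.null(design$x)) {
    x <- design$x
    y <- design$y
    target_cols <- design$target_cols
    distractor_cols <- design$distractor_cols
  } else {
    x <- design
    y <- responses
    target_cols <- grep("^tar_", colnames(x), value = TRUE)
    distractor_cols <- grep("^dis_", colnames(x), value = TRUE)
  }
  if (is.null(y)) {
    abort("`responses` must be supplied with a matrix design.",
          class = "tapgain_invalid_argument")
  }
  y <- as.logical(y)
  if (nrow(x) < 10 * ncol(x)) {
    warn(sprintf("Only %d trials for %d parameters (< 10 per parameter): estimates will be noisy.",
                 nrow(x), ncol(x)))
  }
  core <- fit_binary_glm(x, y, link = link, tol = tol, ridge = ridge)
  structure(
    c(core, list(target_cols = target_cols,
                 distractor_cols = distractor_cols)),
    class = "gain_fit"
  )
}

#' Fit sensory gains from tone and choice tables
#'
#' Convenience front end: [build_design()] then [fit_probit()].
#'
#' @inheritParams build_design
#' @inheritParams fit_probit
#' @return A `gain_fit` object.
#' @export
#' @examples
#' obs <- observer_params(mod_depth_m = 0, listen_mod_depth = 0,
#'                        miss_prob = 0)
#' tones <- generate_trials(300, "exp1", "listen", delta = 0.1, seed = 2)
#' choices <- simulate_choices(tones, NULL, obs, seed = 3)
#' fit <- fit_gains(tones, choices)
#' pool_gains(fit)
fit_gains <- function(tones, choices, link = c("probit", "logit"),
                      tol = 1e-6, ridge = 0) {
  fit_probit(build_design(tones, choices), link = match.arg(link),
             tol = tol, ridge = ridge)
}

#' Pool per-position gains within each role
#'
#' Arithmetic mean of the fitted gains across target positions and across
#' distractor positions.
#'
#' @param est A `gain_fit` (or `modulation_fit`) object.
#' @return Named numeric vector `c(g_target_pooled, g_distractor_pooled)`.
#' @export
pool_gains <- function(est) {
  beta <- est$coefficients
  c(g_target_pooled = mean(beta[est$target_cols]),
    g_distractor_pooled = mean(beta[est$distractor_cols]))
}

#' @export
print.gain_fit <- function(x, ...) {
  pooled <- pool_gains(x)
  cat(sprintf("<gain_fit> %s, %d trials, logLik %.2f%s%s\n", x$link, x$n,
              x$loglik, if (x$converged) "" else " (not converged)",
              if (x$separation) " [separation]" else ""))
  cat(sprintf("  pooled gains: target %.3f, distractor %.3f; bias %.3f\n",
              pooled[1], pooled[2], x$coefficients["(Intercept)"]))
  invisible(x)
}

#' @rdname tapgain-tidiers
#' @export
tidy.gain_fit <- function(x, ...) {
  term <- names(x$coefficients)
  role <- dplyr::case_when(
    term %in% x$target_cols ~ "target",
    term %in% x$distractor_cols ~ "distractor",
    TRUE ~ "bias"
  )
  pos <- suppressWarnings(as.integer(sub("^(tar|dis)_", "", term)))
  tibble(term = term, role = role, position = pos,
         estimate = unname(x$coefficients), std.error = unname(x$se))
}

#' Tidiers for fitted gain and modulation objects
#'
#' `tidy()` returns one row per coefficient; `glance()` one row of fit-level
#' summaries.
#'
#' @param x A `gain_fit` or `modulation_fit` object.
#' @param ... Unused.
#' @name tapgain-tidiers
#' @rdname tapgain-tidiers
#' @export
glance.gain_fit <- function(x, ...) {
  tibble(logLik = x$loglik, logLik_null = x$loglik_null,
         df = length(x$coefficients), nobs = x$n, link = x$link,
         converged = x$converged, separation = x$separation)
}

#' Choice influence as a function of absolute frequency distance
#'
#' Bins target and distractor tones by their absolute log2-distance from the
#' reference and estimates, per bin, the probit regression weight of the
#' tone's frequency sign on the choice. For a probit observer the influence
#' grows with distance for roles that carry gain and stays flat for zero-gain
#' roles.
#'
#' @inheritParams build_design
#' @param n_bins Number of quantile bins of `|f_log2|` per role.
#' @return A tibble with columns `role`, `bin`, `abs_f_lo`, `abs_f_hi`,
#'   `n_tones`, `influence`, `std.error`.
#' @export
influence_by_distance <- function(tones, choices, n_bins = 4) {
  td <- filter(tones, .data$role %in% c("target", "distractor"))
  trials <- sort(unique(td$trial_id))
  ch <- choices$choice[match(trials, choices$trial_id)]
  if (anyNA(ch)) {
    abort("Some trials have no recorded choice.",
          class = "tapgain_data_integrity")
  }
  y <- ch == "high"
  row <- match(td$trial_id, trials)
  out <- list()
  xcols <- list()
  for (r in c("target", "distractor")) {
    sel <- td$role == r
    if (sum(sel) < n_bins) {
      abort(sprintf("Fewer %s tones than bins.", r),
            class = "tapgain_invalid_argument")
    }
    af <- abs(td$f_log2[sel])
    brk <- unique(quantile(af, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(brk) < n_bins + 1) {
      inform("Empty distance bins merged with their neighbours (tied quantiles).")
    }
    bin <- cut(af, breaks = brk, include.lowest = TRUE, labels = FALSE)
    nb <- length(brk) - 1
    for (b in seq_len(nb)) {
      ind <- numeric(nrow(td))
      ind[sel][bin == b] <- sign(td$f_log2[sel][bin == b])
      col <- as.numeric(rowsum(ind, row))
      xcols[[paste(r, b, sep = "_")]] <- col
      out[[paste(r, b, sep = "_")]] <- tibble(
        role = r, bin = b, abs_f_lo = brk[b], abs_f_hi = brk[b + 1],
        n_tones = sum(bin == b)
      )
    }
  }
  x <- cbind(`(Intercept)` = 1, do.call(cbind, xcols))
  fit <- fit_binary_glm(x, y)
  res <- bind_rows(out)
  res$influence <- unname(fit$coefficients[-1])
  res$std.error <- unname(fit$se[-1])
  res
}
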