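#' AIC-based Bayes factor for a per-participant effect
#'
#' Models the per-participant effect values as Gaussian and compares, by
#' AIC, the null model (mean fixed at 0, s.d. free; one parameter) with the
#' effect model (mean and s.d. free; two parameters):
#' `bf = exp((aic_null - aic_effect) / 2)`, equivalently
#' `exp(-1) * (s0^2 / s1^2)^(n/2)` with `s0^2` the mean square and `s1^2`
#' the ML variance. A Bayes factor above 3 is substantial evidence for the
#' effect, below 1/3 substantial evidence for the null; a sample mean of
#' exactly 0 gives `exp(-1)`.
#'
#' @param x Numeric vector of per-participant effect values (n >= 3).
#' @return A one-row tibble: `bf`, `aic_null`, `aic_effect`, `verdict`
#'   (`"favors_null"`, `"inconclusive"`, `"favors_effect"`), `n`.
#' @export
#' @examples
#' aic_bayes_factor(c(-2, -1, 0, 1, 2))$bf # exp(-1)
aic_bayes_factor <- function(x) {
  if (!is.numeric(x) || length(x) < 3 || !all(is.finite(x))) {
    abort("`x` must be >= 3 finite effect values.",
          class = "tapgain_invalid_argument")
  }
  n <- length(x)
  s2_null <- mean(x^2)
  s2_eff <- mean((x - mean(x))^2)
  if (s2_eff <= 0) {
    abort("Zero variance across participants: Gaussian likelihoods are degenerate.",
          class = "tapgain_degenerate_sample")
  }
  ll <- function(s2) -n / 2 * (log(2 * pi * s2) + 1)
  aic_null <- 2 * 1 - 2 * ll(s2_null)
  aic_eff <- 2 * 2 - 2 * ll(s2_eff)
  bf <- exp((aic_null - aic_eff) / 2)
  verdict <- if (bf < 1 / 3) {
    "favors_null"
  } else if (bf > 3) {
    "favors_effect"
  } else {
    "inconclusive"
  }
  tibble(bf = bf, aic_null = aic_null, aic_effect = aic_eff,
         verdict = verdict, n = n)
}

# Fisher's approximation to the ML von Mises concentration for mean
# resultant length r.
kappa_from_rbar <- function(r) {
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

#' Watson-Williams test for equal mean directions
#'
#' Parametric one-way comparison of the mean directions of two circular
#' samples (radians), assuming von Mises populations with common
#' concentration. Low concentration (mean resultant length below ~0.45)
#' undermines the test's validity and is flagged.
#'
#' @param phases_a,phases_b Numeric vectors of phases in radians (n >= 5
#'   each).
#' @return A one-row tibble: `statistic` (F), `df1`, `df2`, `p.value`,
#'   `r_bar`, `kappa`, `low_concentration`.
#' @export
watson_williams <- function(phases_a, phases_b) {
  if (length(phases_a) < 5 || length(phases_b) < 5) {
    abort("Each group needs at least 5 phases.",
          class = "tapgain_invalid_argument")
  }
  resultant <- function(p) sqrt(sum(cos(p))^2 + sum(sin(p))^2)
  r1 <- resultant(phases_a)
  r2 <- resultant(phases_b)
  rc <- resultant(c(phases_a, phases_b))
  n <- length(phases_a) + length(phases_b)
  r_bar <- (r1 + r2) / n
  low <- r_bar < 0.45
  if (low) {
    warn("Mean resultant length below 0.45: the Watson-Williams F approximation is unreliable.",
         class = "tapgain_low_concentration")
  }
  kappa <- kappa_from_rbar(r_bar)
  k_corr <- 1 + 3 / (8 * kappa)
  f_stat <- k_corr * (n - 2) * (r1 + r2 - rc) / (n - (r1 + r2))
  f_stat <- max(f_stat, 0)
  tibble(statistic = f_stat, df1 = 1, df2 = n - 2,
         p.value = pf(f_stat, 1, n - 2, lower.tail = FALSE),
         r_bar = r_bar, kappa = kappa, low_concentration = low)
}

t_tidy <- function(est, stat, df, p, method) {
  tibble(estimate = est, statistic = stat, df = df, p.value = p,
         method = method)
}

#' Standard group-level tests
#'
#' Thin tidy wrappers around the classical two-sided tests used at the
#' group level, returning one-row tibbles. Degenerate zero-variance samples
#' with zero mean difference return a statistic of 0 rather than an error.
#'
#' @param x,y Numeric vectors (matched lengths for the paired test).
#' @param mu Null value for the one-sample test.
#' @return A one-row tibble with `estimate`, `statistic`, `df`, `p.value`,
#'   `method`.
#' @name group-tests
NULL

#' @rdname group-tests
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) {
    abort("Paired samples must have matched lengths.",
          class = "tapgain_invalid_argument")
  }
  one_sample_t(x - y, mu = 0, .method = "paired t-test")
}

#' @rdname group-tests
#' @export
one_sample_t <- function(x, mu = 0, .method = "one-sample t-test") {
  if (length(x) < 2) {
    abort("Need at least 2 values.", class = "tapgain_invalid_argument")
  }
  if (sd(x) == 0) {
    d <- mean(x) - mu
    return(t_tidy(mean(x), if (d == 0) 0 else sign(d) * Inf,
                  length(x) - 1, if (d == 0) 1 else 0, .method))
  }
  tt <- t.test(x, mu = mu)
  t_tidy(unname(tt$estimate), unname(tt$statistic), unname(tt$parameter),
         tt$p.value, .method)
}

#' @rdname group-tests
#' @export
two_sample_t <- function(x, y) {
  if (sd(c(x, y)) == 0) {
    return(t_tidy(0, 0, length(x) + length(y) - 2, 1, "two-sample t-test"))
  }
  tt <- t.test(x, y, var.equal = TRUE)
  t_tidy(unname(tt$estimate[1] - tt$estimate[2]), unname(tt$statistic),
         unname(tt$parameter), tt$p.value, "two-sample t-test")
}

#' @rdname group-tests
#' @export
pearson_r <- function(x, y) {
  ct <- suppressWarnings(cor.test(x, y))
  tibble(estimate = unname(ct$estimate), statistic = unname(ct$statistic),
         df = unname(ct$parameter), p.value = ct$p.value,
         method = "Pearson correlation")
}

#' Two-by-two repeated-measures ANOVA
#'
#' Within-subject ANOVA for a complete 2 x 2 design, computed from
#' per-subject cell means via orthogonal contrasts (exact for two-level
#' factors: each F is the square of the paired t on the corresponding
#' contrast, with df (1, n - 1); no sphericity correction is needed at
#' df = 1).
#'
#' @param data A data frame in long format.
#' @param subject,f1,f2,value Columns (tidy-select) holding the subject id,
#'   the two two-level factors, and the response.
#' @return A tibble with one row per effect (`f1`, `f2`, `interaction`):
#'   `effect`, `statistic` (F), `df1`, `df2`, `p.value`.
#' @export
rm_anova_2x2 <- function(data, subject, f1, f2, value) {
  df <- tibble(
    s = dplyr::pull(data, {{ subject }}),
    a = as.character(dplyr::pull(data, {{ f1 }})),
    b = as.character(dplyr::pull(data, {{ f2 }})),
    v = dplyr::pull(data, {{ value }})
  )
  la <- sort(unique(df$a))
  lb <- sort(unique(df$b))
  if (length(la) != 2 || length(lb) != 2) {
    abort("Both factors must have exactly two levels.",
          class = "tapgain_invalid_argument")
  }
  cells <- df |>
    group_by(.data$s, .data$a, .data$b) |>
    summarise(v = mean(.data$v), .groups = "drop") |>
    tidyr::pivot_wider(names_from = c("a", "b"), values_from = "v")
  cell_cols <- c(paste(la[1], lb[1], sep = "_"), paste(la[1], lb[2], sep = "_"),
                 paste(la[2], lb[1], sep = "_"), paste(la[2], lb[2], sep = "_"))
  if (!all(cell_cols %in% names(cells)) ||
      anyNA(cells[cell_cols])) {
    abort("Incomplete 2x2 within-subject cells.",
          class = "tapgain_invalid_argument")
  }
  m <- as.matrix(cells[cell_cols])
  contrasts <- list(
    (m[, 3] + m[, 4] - m[, 1] - m[, 2]) / 2,  # main effect of f1
    (m[, 2] + m[, 4] - m[, 1] - m[, 3]) / 2,  # main effect of f2
    (m[, 1] - m[, 2] - m[, 3] + m[, 4]) / 2   # interaction
  )
  n <- nrow(m)
  effect_names <- c(rlang::as_name(rlang::enquo(f1)),
                    rlang::as_name(rlang::enquo(f2)), "interaction")
  purrr::map2_dfr(contrasts, effect_names, function(cc, nm) {
    tt <- one_sample_t(cc)
    f_stat <- tt$statistic^2
    tibble(effect = nm, statistic = f_stat, df1 = 1, df2 = n - 1,
           p.value = pf(f_stat, 1, n - 1, lower.tail = FALSE))
  })
}
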