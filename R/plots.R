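#' Plot per-position sensory gains
#'
#' Fitted gain (with +/- 1 s.e. bars) for each target and distractor
#' position, with the pooled gains as dashed lines.
#'
#' @param object A `gain_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gain_fit <- function(object, ...) {
  td <- filter(tidy(object), .data$role != "bias")
  pooled <- tibble(role = c("target", "distractor"),
                   pooled = unname(pool_gains(object)))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$position, y = .data$estimate,
                                   colour = .data$role)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3,
                        colour = "grey60") +
    ggplot2::geom_hline(data = pooled,
                        ggplot2::aes(yintercept = .data$pooled,
                                     colour = .data$role),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - .data$std.error,
      ymax = .data$estimate + .data$std.error
    )) +
    ggplot2::labs(x = "Position in stream", y = "Sensory gain (per log2 unit)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the sliding-octile gain profile
#'
#' Sensory gain as a function of the quantile of tone-tap simultaneity
#' (0 = most synchronous windows).
#'
#' @param object An `octile_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.octile_profile <- function(object, ...) {
  long <- tibble(
    centre = rep((object$q_lo + object$q_hi) / 2, 2),
    gain = c(object$g_target, object$g_distractor),
    se = c(object$se_target, object$se_distractor),
    role = rep(c("target", "distractor"), each = nrow(object))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$centre, y = .data$gain,
                                     colour = .data$role,
                                     fill = .data$role)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$gain - .data$se,
                                      ymax = .data$gain + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Simultaneity quantile (0 = synchronous with taps)",
                  y = "Sensory gain (per log2 unit)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a staircase trajectory
#'
#' Stimulus level per trial, coloured by response accuracy, with the
#' converged level as a horizontal line.
#'
#' @param object A `staircase_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.staircase_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$trial, y = .data$delta)) +
    ggplot2::geom_step(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$correct), size = 0.8) +
    ggplot2::geom_hline(yintercept = object$delta, linetype = "dashed") +
    ggplot2::labs(x = "Trial", y = "Target-mean offset (log2 units)",
                  colour = "Correct") +
    ggplot2::theme_minimal()
}
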