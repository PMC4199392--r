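tones_required_cols <- c("trial_id", "experiment", "condition",
                         "jitter_condition", "f_tar_mean_log2", "role",
                         "index_in_role", "nominal_onset_ms", "jitter_ms",
                         "onset_ms", "duration_ms", "f_log2")

check_cols <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    abort(paste0(what, " table is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "tapgain_schema_error")
  }
  invisible(df)
}

#' Validate the schema of the pipeline tables
#'
#' Checks required columns (naming any offending column), tap-time
#' monotonicity within trials (naming the trial), and choice coding.
#'
#' @param tones,taps,choices The respective tibbles.
#' @return The input, invisibly; signals a `tapgain_schema_error` or
#'   `tapgain_data_integrity` condition on failure.
#' @name validators
NULL

#' @rdname validators
#' @export
validate_tones <- function(tones) {
  check_cols(tones, tones_required_cols, "tones")
  bad_role <- setdiff(unique(tones$role),
                      c("reference", "target", "distractor"))
  if (length(bad_role) > 0) {
    abort(paste0("Unknown tone role(s): ", paste(bad_role, collapse = ", ")),
          class = "tapgain_schema_error")
  }
  invisible(tones)
}

#' @rdname validators
#' @export
validate_taps <- function(taps) {
  check_cols(taps, c("trial_id", "tap_time_ms"), "taps")
  if (nrow(taps) > 1) {
    ord <- order(taps$trial_id, seq_len(nrow(taps)))
    sorted_ids <- taps$trial_id[ord]
    same <- diff(as.numeric(factor(sorted_ids))) == 0
    dt <- diff(taps$tap_time_ms[ord])
    if (any(same & dt <= 0)) {
      bad <- sorted_ids[which(same & dt <= 0)[1]]
      abort(paste0("Tap times are not strictly increasing in trial ", bad, "."),
            class = "tapgain_data_integrity")
    }
  }
  invisible(taps)
}

#' @rdname validators
#' @export
validate_choices <- function(choices) {
  check_cols(choices, c("trial_id", "choice"), "choices")
  if (!all(choices$choice %in% c("high", "low"))) {
    abort("`choice` must be 'high' or 'low'.",
          class = "tapgain_schema_error")
  }
  if (anyDuplicated(choices$trial_id)) {
    bad <- choices$trial_id[duplicated(choices$trial_id)][1]
    abort(paste0("Duplicated choice for trial ", bad, "."),
          class = "tapgain_data_integrity")
  }
  invisible(choices)
}

#' Write and read a simulated dataset as delimited text
#'
#' Writes `trials.csv`, `tones.csv`, `taps.csv`, `choices.csv` and
#' `beats.csv` into a directory; `read_dataset()` reads and validates them
#' back. The round trip is lossless.
#'
#' @param data A list with `trials`, `tones`, `taps`, `choices` (as from
#'   [simulate_dataset()]).
#' @param dir Directory path (created if absent).
#' @param beat_times Beat times stored alongside the tables.
#' @return `write_dataset()` the directory invisibly; `read_dataset()` the
#'   list of tibbles (including `beats`).
#' @export
write_dataset <- function(data, dir, beat_times = make_reference_beat()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  validate_tones(data$tones)
  validate_taps(data$taps)
  validate_choices(data$choices)
  readr::write_csv(data$trials, file.path(dir, "trials.csv"))
  readr::write_csv(data$tones, file.path(dir, "tones.csv"))
  readr::write_csv(data$taps, file.path(dir, "taps.csv"))
  readr::write_csv(data$choices, file.path(dir, "choices.csv"))
  readr::write_csv(tibble(beat_index = seq_along(beat_times) - 1L,
                          beat_time_ms = beat_times),
                   file.path(dir, "beats.csv"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  rd <- function(name, types) {
    readr::read_csv(file.path(dir, name), col_types = types,
                    progress = FALSE)
  }
  tones <- rd("tones.csv", readr::cols(
    trial_id = "i", experiment = "c", condition = "c",
    jitter_condition = "c", f_tar_mean_log2 = "d", role = "c",
    index_in_role = "i", nominal_onset_ms = "d", jitter_ms = "d",
    onset_ms = "d", duration_ms = "d", f_log2 = "d",
    .default = "d"
  ))
  taps <- rd("taps.csv", readr::cols(
    trial_id = "i", tap_index = "i", tap_time_ms = "d", .default = "l"
  ))
  choices <- rd("choices.csv", readr::cols(
    trial_id = "i", choice = "c", p_high_true = "d", correct = "l",
    .default = "d"
  ))
  trials <- rd("trials.csv", readr::cols(
    trial_id = "i", experiment = "c", condition = "c",
    jitter_condition = "c", f_tar_mean_log2 = "d"
  ))
  beats <- rd("beats.csv", readr::cols(beat_index = "i",
                                       beat_time_ms = "d"))
  validate_tones(tones)
  validate_taps(taps)
  validate_choices(choices)
  list(trials = trials, tones = tones, taps = taps, choices = choices,
       beats = beats)
}

#' Write and read a run configuration
#'
#' Observer parameters, design settings and seeds as a plain-text YAML file
#' that round-trips losslessly.
#'
#' @param config A named list (may include an `observer_params` element).
#' @param path File path.
#' @return `write_config()` the path invisibly; `read_config()` the list
#'   (with the observer restored as `observer_params`).
#' @export
write_config <- function(config, path) {
  strip <- function(x) {
    if (inherits(x, "observer_params")) {
      x <- unclass(x)
      attr(x, "tapgain_class") <- NULL
      c(list(.class = "observer_params"), x)
    } else if (is.list(x)) {
      lapply(x, strip)
    } else {
      x
    }
  }
  yaml::write_yaml(strip(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  restore <- function(x) {
    if (is.list(x)) {
      if (identical(x$.class, "observer_params")) {
        return(do.call(observer_params, x[setdiff(names(x), ".class")]))
      }
      lapply(x, restore)
    } else {
      x
    }
  }
  restore(yaml::read_yaml(path))
}

#' Serialize a fitted estimate as structured text
#'
#' Writes the coefficients, standard errors, log-likelihoods and fit
#' metadata of a `gain_fit` or `modulation_fit` to JSON.
#'
#' @param fit A `gain_fit` or `modulation_fit`.
#' @param path File path.
#' @return `write_estimate()` the path invisibly; `read_estimate()` a list.
#' @export
write_estimate <- function(fit, path) {
  if (!inherits(fit, c("gain_fit", "modulation_fit"))) {
    abort("`fit` must be a gain_fit or modulation_fit.",
          class = "tapgain_invalid_argument")
  }
  payload <- list(
    type = class(fit)[1],
    coefficients = as.list(fit$coefficients),
    se = as.list(fit$se),
    loglik = if (inherits(fit, "modulation_fit")) fit$loglik_mod else fit$loglik,
    loglik_null = fit$loglik_null,
    converged = fit$converged,
    separation = fit$separation,
    n = fit$n,
    link = fit$link
  )
  if (inherits(fit, "modulation_fit")) {
    payload$loglik_base <- fit$loglik_base
    payload$mod_strength <- as.list(fit$mod_strength)
    payload$pref_phase_rad <- as.list(fit$pref_phase_rad)
    payload$include_sine <- fit$include_sine
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_estimate
#' @export
read_estimate <- function(path) {
  jsonlite::fromJSON(path)
}
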