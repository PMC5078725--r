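#' Synthesize a 300 Hz gaze trace for one trial
#'
#' Builds an eye-position time series emulating a video eye tracker
#' sampling at 300 Hz: Gaussian fixation noise around screen centre, then
#' (for responded trials) a minimum-jerk horizontal displacement of the
#' trial's amplitude toward its saccade direction, starting at stimulus
#' onset plus the trial's latency. Saccade duration follows the main
#' sequence (about 2.2 ms per degree plus 21 ms). The ground-truth onset
#' is recorded in the result for detector validation.
#'
#' Contaminant trials produce their defining shapes: no-response trials
#' stay in the fixation noise band; micromovement trials make a small
#' (< 2 degree) displacement at the trial latency.
#'
#' @param trial One row of a trial table (`rt_ms`, `amplitude_deg`,
#'   `direction`; NA `rt_ms` means no response).
#' @param stimulus_onset_ms Stimulus onset relative to trace start (ms).
#' @param duration_ms Total trace duration (ms).
#' @param noise_sd_deg SD of additive Gaussian sample noise (degrees);
#'   default 0.05, typical RMS noise of a 300 Hz video tracker.
#' @param sample_rate_hz Sampling rate (default 300).
#' @return A list of class `gaze_trace`: `t_ms`, `x_deg`, `y_deg`,
#'   `stimulus_onset_ms`, `true_onset_ms` (NA for no-response trials),
#'   plus the trial's `participant_id`/`trial` if present.
#' @examples
#' set.seed(1)
#' tr <- tibble::tibble(rt_ms = 250, amplitude_deg = 12,
#'                      direction = "right")
#' g <- synthesize_gaze_trace(tr, noise_sd_deg = 0)
#' tail(g$x_deg, 1)
#' @export
synthesize_gaze_trace <- function(trial, stimulus_onset_ms = 500,
                                  duration_ms = 1800,
                                  noise_sd_deg = 0.05,
                                  sample_rate_hz = 300) {
  dt <- 1000 / sample_rate_hz
  t_ms <- seq(0, duration_ms, by = dt)
  n <- length(t_ms)
  x <- rnorm(n, 0, noise_sd_deg)
  y <- rnorm(n, 0, noise_sd_deg)
  true_onset <- NA_real_
  amp <- trial$amplitude_deg
  if (!is.na(trial$rt_ms) && !is.na(amp) && amp > 0) {
    sign <- if (trial$direction == "left") -1 else 1
    onset <- stimulus_onset_ms + trial$rt_ms
    sac_dur <- 21 + 2.2 * amp                 # main-sequence duration
    tau <- (t_ms - onset) / sac_dur
    tau <- pmin(pmax(tau, 0), 1)
    profile <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5   # minimum jerk
    x <- x + sign * amp * profile
    true_onset <- onset
  }
  col <- function(nm, default) {
    if (nm %in% names(trial)) trial[[nm]][1] else default
  }
  out <- list(t_ms = t_ms, x_deg = x, y_deg = y,
              stimulus_onset_ms = stimulus_onset_ms,
              true_onset_ms = true_onset,
              participant_id = col("participant_id", NA_character_),
              trial = col("trial", NA_integer_))
  structure(out, class = "gaze_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf("<gaze_trace> %d samples, stimulus at %.0f ms, true onset %s\n",
              length(x$t_ms), x$stimulus_onset_ms,
              if (is.na(x$true_onset_ms)) "none"
              else sprintf("%.1f ms", x$true_onset_ms)))
  invisible(x)
}

#' Convert a gaze trace to / from the tidy gaze table
#'
#' @param trace A `gaze_trace`.
#' @return A tibble in the gaze CSV dialect:
#'   `participant_id, trial, t_ms, x_deg, y_deg`.
#' @export
gaze_to_table <- function(trace) {
  stopifnot(inherits(trace, "gaze_trace"))
  tibble(participant_id = trace$participant_id, trial = trace$trial,
         t_ms = trace$t_ms, x_deg = trace$x_deg, y_deg = trace$y_deg)
}

#' @rdname gaze_to_table
#' @param gaze_table A gaze-dialect tibble for a single trial.
#' @param stimulus_onset_ms Stimulus onset (ms) for the trial.
#' @export
gaze_from_table <- function(gaze_table, stimulus_onset_ms) {
  stopifnot(all(c("t_ms", "x_deg", "y_deg") %in% names(gaze_table)))
  structure(
    list(t_ms = gaze_table$t_ms, x_deg = gaze_table$x_deg,
         y_deg = gaze_table$y_deg,
         stimulus_onset_ms = stimulus_onset_ms,
         true_onset_ms = NA_real_,
         participant_id = if ("participant_id" %in% names(gaze_table))
           gaze_table$participant_id[1] else NA_character_,
         trial = if ("trial" %in% names(gaze_table))
           gaze_table$trial[1] else NA_integer_),
    class = "gaze_trace"
  )
}
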