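#' Horizontal gaze velocity by smoothed central differences
#'
#' Applies a short moving-average smooth to the horizontal position channel
#' and differentiates by central finite differences, returning a velocity
#' series (deg/s) the same length as the input with endpoint values
#' replicated. Only the horizontal channel is used: the task response is a
#' left/right saccade.
#'
#' @param trace A `gaze_trace` (see [synthesize_gaze_trace()] /
#'   [gaze_from_table()]).
#' @param smooth_window Moving-average window in samples (odd, default 3;
#'   1 disables smoothing).
#' @return Numeric velocity (deg/s), one value per sample.
#' @export
estimate_velocity <- function(trace, smooth_window = 3L) {
  stopifnot(inherits(trace, "gaze_trace"))
  n <- length(trace$t_ms)
  if (n < 5L) stop("trace too short for velocity estimation", call. = FALSE)
  if (any(diff(trace$t_ms) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  x <- trace$x_deg
  if (smooth_window > 1L) {
    k <- as.integer(smooth_window)
    if (k %% 2L == 0L) stop("smooth_window must be odd", call. = FALSE)
    kern <- rep(1 / k, k)
    sm <- stats::filter(x, kern, sides = 2)
    x <- as.numeric(sm)
    # moving average is undefined at the edges; fall back to raw samples
    h <- (k - 1L) %/% 2L
    x[seq_len(h)] <- trace$x_deg[seq_len(h)]
    x[(n - h + 1L):n] <- trace$x_deg[(n - h + 1L):n]
  }
  v <- numeric(n)
  idx <- 2:(n - 1L)
  v[idx] <- (x[idx + 1L] - x[idx - 1L]) /
    (trace$t_ms[idx + 1L] - trace$t_ms[idx - 1L]) * 1000
  v[1L] <- v[2L]
  v[n] <- v[n - 1L]
  v
}

#' Detect saccades with an iterative adaptive velocity threshold
#'
#' Velocity-threshold event detection in the style of noise-adaptive
#' saccade detectors: starting from `pt0` deg/s, the threshold is
#' iteratively re-estimated as mean + 6 SD of the sub-threshold velocity
#' samples until it changes by less than 1 deg/s. Contiguous
#' supra-threshold runs of at least `min_samples` samples become events;
#' onset and offset are extended outwards to the nearest local minimum of
#' absolute velocity. Amplitude is the horizontal displacement between
#' onset and offset samples; direction its sign.
#'
#' If the threshold has not converged after `max_iter` iterations the
#' detector falls back to a fixed 30 deg/s threshold and flags the result.
#'
#' @param trace A `gaze_trace`.
#' @param pt0 Initial peak threshold (deg/s).
#' @param min_samples Minimum event length in samples.
#' @param smooth_window Passed to [estimate_velocity()].
#' @param max_iter Threshold iterations before the fixed fallback.
#' @return A tibble of class `saccade_events` with columns `onset_ms`,
#'   `offset_ms`, `amplitude_deg`, `direction`, `peak_velocity`; the final
#'   threshold and a `fallback` flag are attached as attributes.
#' @examples
#' set.seed(1)
#' tr <- tibble::tibble(rt_ms = 250, amplitude_deg = 12, direction = "right")
#' g <- synthesize_gaze_trace(tr)
#' detect_saccades(g)
#' @export
detect_saccades <- function(trace, pt0 = 100, min_samples = 3L,
                            smooth_window = 3L, max_iter = 50L) {
  v <- estimate_velocity(trace, smooth_window)
  av <- abs(v)
  pt <- pt0
  fallback <- FALSE
  for (i in seq_len(max_iter)) {
    below <- av[av < pt]
    if (length(below) < 2L) { fallback <- TRUE; break }
    pt_new <- mean(below) + 6 * stats::sd(below)
    if (abs(pt_new - pt) < 1) { pt <- pt_new; break }
    pt <- pt_new
    if (i == max_iter) fallback <- TRUE
  }
  if (fallback) pt <- 30

  above <- av > pt
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_samples
  ev_start <- starts[keep]
  ev_end <- ends[keep]

  to_local_min <- function(i, dir) {
    repeat {
      j <- i + dir
      if (j < 1L || j > length(av)) return(i)
      if (av[j] >= av[i]) return(i)
      i <- j
    }
  }
  # noise floor for the onset refinement: quiet-sample statistics
  quiet <- av[av < pt]
  noise_floor <- if (length(quiet) >= 2L) {
    mean(quiet) + 3 * stats::sd(quiet)
  } else {
    0
  }
  n_ev <- length(ev_start)
  onset <- offset <- amp <- pk <- numeric(n_ev)
  dirn <- character(n_ev)
  for (e in seq_len(n_ev)) {
    s0 <- to_local_min(ev_start[e], -1L)
    t <- to_local_min(ev_end[e], +1L)
    # onset refinement: walk forward from the local minimum to the first
    # sample whose speed clears the onset floor (the larger of the noise
    # floor and 5% of the event's peak velocity), then take the sample
    # before it -- the interval in which the movement actually began
    floor_e <- max(noise_floor, 0.05 * max(av[ev_start[e]:ev_end[e]]))
    s <- s0
    while (s < ev_end[e] && av[s] < floor_e) s <- s + 1L
    if (s > s0) s <- s - 1L
    onset[e] <- trace$t_ms[s]
    offset[e] <- trace$t_ms[t]
    disp <- trace$x_deg[t] - trace$x_deg[s]
    amp[e] <- abs(disp)
    dirn[e] <- if (disp < 0) "left" else "right"
    pk[e] <- max(av[ev_start[e]:ev_end[e]])
  }
  out <- tibble(onset_ms = onset, offset_ms = offset, amplitude_deg = amp,
                direction = dirn, peak_velocity = pk)
  attr(out, "threshold") <- pt
  attr(out, "fallback") <- fallback
  class(out) <- c("saccade_events", class(out))
  out
}

#' Extract the behavioural response from detected saccades
#'
#' The first detected eye movement after stimulus onset whose amplitude
#' reaches the micromovement cutoff (2 degrees by default) is the
#' participant's response; smaller earlier movements are skipped as
#' fixation micromovements. Latency is the event onset minus stimulus
#' onset.
#'
#' @param events A `saccade_events` tibble (sorted by onset).
#' @param trace The `gaze_trace` the events came from (provides
#'   `stimulus_onset_ms`).
#' @param min_amplitude_deg Micromovement cutoff (degrees).
#' @return A one-row tibble `direction`, `rt_ms`, `amplitude_deg`, or
#'   `NULL` when no qualifying movement exists.
#' @export
extract_response <- function(events, trace, min_amplitude_deg = 2) {
  onset0 <- trace$stimulus_onset_ms
  cand <- events[events$onset_ms > onset0 &
                   events$amplitude_deg >= min_amplitude_deg, ,
                 drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  first <- cand[which.min(cand$onset_ms), ]
  tibble(direction = first$direction,
         rt_ms = first$onset_ms - onset0,
         amplitude_deg = first$amplitude_deg)
}

#' Detect responses for a batch of gaze traces
#'
#' Runs [detect_saccades()] and [extract_response()] over a list of traces
#' and assembles per-trial response rows in the trial table dialect
#' (without the generator's `route` column). Trials with no qualifying
#' movement get `NA` latency/direction.
#'
#' @param traces List of `gaze_trace` objects.
#' @param ... Passed to [detect_saccades()].
#' @param min_amplitude_deg Micromovement cutoff for [extract_response()].
#' @return A tibble `participant_id, trial, rt_ms, amplitude_deg,
#'   direction`.
#' @export
detect_responses <- function(traces, ..., min_amplitude_deg = 2) {
  rows <- purrr::map(traces, function(tr) {
    ev <- detect_saccades(tr, ...)
    resp <- extract_response(ev, tr, min_amplitude_deg = min_amplitude_deg)
    if (is.null(resp)) {
      resp <- tibble(direction = NA_character_, rt_ms = NA_real_,
                     amplitude_deg = NA_real_)
    }
    dplyr::bind_cols(
      tibble(participant_id = tr$participant_id, trial = tr$trial),
      resp
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::select("participant_id", "trial", "rt_ms", "amplitude_deg",
                  "direction")
}
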