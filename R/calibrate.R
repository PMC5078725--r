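#' Large-N simulation oracle: group-level observables of a parameter set
#'
#' Brute-force estimate of the observables the generator is calibrated
#' against, obtained by simulating a large synthetic cohort and running the
#' exact analysis pipeline (exclusion filters, congruence effect,
#' conditional accuracy functions) on it:
#' mean raw-RT congruence effect on correct trials (ms), congruent and
#' incongruent accuracy, first-septile incongruent accuracy (vincentized
#' over participants), and the overall exclusion fraction.
#'
#' Because the first-septile accuracy depends on how many trials fall in
#' each bin, the oracle keeps the emulated session length (default 300
#' trials per participant) and grows the cohort instead, so its
#' vincentized estimates target the same quantity the study-sized pipeline
#' measures.
#'
#' @param gp A [group_params()] object.
#' @param n_trials Total trials to simulate (default 1e5).
#' @param trials_per_session Session length per synthetic participant; the
#'   cohort size is `ceiling(n_trials / trials_per_session)`.
#' @param qc A [qc_config()].
#' @param seed Integer seed.
#' @param n_bins Bins for the conditional accuracy function.
#' @return A one-row tibble with columns `congruence_effect_ms`,
#'   `acc_congruent`, `acc_incongruent`, `caf1_incongruent`,
#'   `exclusion_rate` (accuracies and rates as proportions in `[0, 1]`).
#' @examples
#' simulate_observables(default_group_params("young"), n_trials = 4000,
#'                      seed = 1)
#' @export
simulate_observables <- function(gp, n_trials = 1e5,
                                 trials_per_session = 300L,
                                 qc = qc_config(), seed = 1L, n_bins = 7L) {
  stopifnot(inherits(gp, "group_params"))
  per <- ceiling(trials_per_session / 4) * 4  # keep 2x2 cells exact
  n_participants <- as.integer(ceiling(n_trials / per))
  cfg <- study_config(groups = list(group = gp),
                      n_participants = c(group = n_participants),
                      n_blocks = 1L, trials_per_block = as.integer(per),
                      seed = seed)
  trials <- simulate_session(cfg)
  res <- apply_exclusions(trials, qc)
  ce <- congruence_effect(res$trials)
  caf <- compute_caf(res$trials, n_bins = n_bins)
  acc <- res$trials |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(acc = mean(.data$correct), .groups = "drop")
  caf1 <- caf$by_group |>
    dplyr::filter(.data$condition == "incongruent", .data$bin == 1L)
  tibble(
    congruence_effect_ms = ce$by_group$mean_effect_ms[1],
    acc_congruent = acc$acc[acc$condition == "congruent"],
    acc_incongruent = acc$acc[acc$condition == "incongruent"],
    caf1_incongruent = caf1$mean_accuracy,
    exclusion_rate = res$report$overall$fraction_removed
  )
}

# Which generator parameter moves which observable, and in which direction.
# Bounds chosen generously around the physiologically plausible range.
calibration_map <- function() {
  list(
    congruence_effect_ms = list(param = "delta0", lower = 0, upper = 250,
                                increasing = TRUE),
    acc_incongruent = list(param = "capture_prob", lower = 0, upper = 1,
                           increasing = FALSE),
    caf1_incongruent = list(param = "mu_log_auto", lower = log(150),
                            upper = log(650), increasing = TRUE),
    acc_congruent = list(param = "lapse_rate", lower = 0, upper = 0.3,
                         increasing = FALSE),
    exclusion_rate = list(param = "contaminant_scale", lower = 0, upper = 8,
                          increasing = TRUE)
  )
}

#' Calibrate generator parameters to target observables
#'
#' Tunes one generator parameter per target observable by bisection against
#' the large-N simulation oracle, sweeping over the observables until all
#' achieved values sit within `tol` of their targets. Every oracle
#' evaluation reuses the same seed (common random numbers), which makes the
#' parameter-to-observable map deterministic and near-monotone so that
#' bisection is well behaved. Supported observables and the parameter each
#' one drives:
#' `congruence_effect_ms` (ms) via `delta0`; `acc_incongruent` via
#' `capture_prob`; `caf1_incongruent` via `mu_log_auto`; `acc_congruent`
#' via `lapse_rate`; `exclusion_rate` via a common scale on the four
#' contaminant rates.
#'
#' @param targets Named numeric vector of target observables (accuracies
#'   and rates as proportions; the congruence effect in ms).
#' @param gp0 Starting [group_params()].
#' @param n_trials Oracle size per evaluation (default 1e5).
#' @param trials_per_session Session length per synthetic participant in
#'   the oracle (default 300, the emulated design).
#' @param tol Absolute tolerance: proportions 0.01; the congruence effect
#'   uses `tol_ms`.
#' @param tol_ms Tolerance on the congruence effect (ms).
#' @param max_sweeps Full passes over the observables before giving up.
#' @param max_bisect Bisection steps per observable per sweep.
#' @param qc [qc_config()] used inside the oracle.
#' @param seed Oracle seed (held fixed across evaluations).
#' @param verbose Print per-sweep progress.
#' @return A list of class `calibration` with elements `params` (the
#'   calibrated `group_params`), `achieved` (oracle observables at the
#'   solution), `targets`, and `converged`. If the budget is exhausted the
#'   best point found is returned with `converged = FALSE` and a warning.
#' @examples
#' \donttest{
#' cal <- calibrate_group(c(acc_incongruent = 0.88),
#'                        default_group_params("young"),
#'                        n_trials = 2e4)
#' cal$achieved
#' }
#' @export
calibrate_group <- function(targets, gp0 = default_group_params("young"),
                            n_trials = 1e5, trials_per_session = 300L,
                            tol = 0.01, tol_ms = 1, max_sweeps = 8L,
                            max_bisect = 12L, qc = qc_config(), seed = 1L,
                            verbose = FALSE) {
  map <- calibration_map()
  unknown <- setdiff(names(targets), names(map))
  if (length(unknown)) {
    stop("unsupported calibration observable(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  gp <- gp0

  get_par <- function(gp, param) {
    if (param == "contaminant_scale") 1 else gp[[param]]
  }
  set_par <- function(gp, param, value) {
    if (param == "contaminant_scale") {
      update_group_params(gp, contaminant_scale = value)
    } else {
      args <- list(gp); args[[param]] <- value
      do.call(update_group_params, args)
    }
  }
  eval_obs <- function(gp) {
    simulate_observables(gp, n_trials = n_trials,
                         trials_per_session = trials_per_session, qc = qc,
                         seed = seed)
  }
  tol_for <- function(obs) if (obs == "congruence_effect_ms") tol_ms else tol

  achieved <- eval_obs(gp)
  for (sweep in seq_len(max_sweeps)) {
    off <- vapply(names(targets), function(o) {
      abs(achieved[[o]] - targets[[o]]) > tol_for(o)
    }, logical(1))
    if (!any(off)) break
    for (obs in names(targets)[off]) {
      m <- map[[obs]]
      lo <- m$lower; hi <- m$upper
      gp_try <- gp
      for (it in seq_len(max_bisect)) {
        mid <- (lo + hi) / 2
        gp_try <- set_par(gp, m$param, mid)
        val <- eval_obs(gp_try)[[obs]]
        if (abs(val - targets[[obs]]) <= tol_for(obs) / 2) break
        go_up <- (val < targets[[obs]]) == m$increasing
        if (go_up) lo <- mid else hi <- mid
      }
      gp <- gp_try
      achieved <- eval_obs(gp)
      if (verbose) {
        message(sprintf("sweep %d: %s -> %s = %.4g (target %.4g)",
                        sweep, m$param, obs, achieved[[obs]],
                        targets[[obs]]))
      }
    }
  }
  off <- vapply(names(targets), function(o) {
    abs(achieved[[o]] - targets[[o]]) > tol_for(o)
  }, logical(1))
  converged <- !any(off)
  if (!converged) {
    warning("calibration budget exhausted; returning best point (off: ",
            paste(names(targets)[off], collapse = ", "), ")",
            call. = FALSE)
  }
  structure(list(params = gp, achieved = achieved, targets = targets,
                 converged = converged),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat("<calibration", if (x$converged) "(converged)>" else "(NOT converged)>",
      "\n")
  for (o in names(x$targets)) {
    cat(sprintf("  %-22s target %.4g achieved %.4g\n", o, x$targets[[o]],
                x$achieved[[o]]))
  }
  invisible(x)
}
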