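#' Assign reaction times to equal-count quantile bins (septiles)
#'
#' Rank-orders the reaction times (stably: ties broken by original
#' position) and splits them into `n_bins` bins with counts as equal as
#' possible; when `length(rts)` is not a multiple of `n_bins`, the
#' remainder `r` puts one extra trial in each of the first `r` (fastest)
#' bins. Deterministic by construction.
#'
#' @param rts Numeric reaction times.
#' @param n_bins Number of bins (default 7, septiles).
#' @return Integer bin index (1 = fastest) per input element, in input
#'   order.
#' @examples
#' bin_septiles(c(350, 310, 290, 400, 330, 305, 360), n_bins = 7)
#' @export
bin_septiles <- function(rts, n_bins = 7L) {
  n <- length(rts)
  if (n < n_bins) {
    stop("need at least as many trials (", n, ") as bins (", n_bins, ")",
         call. = FALSE)
  }
  if (anyNA(rts)) stop("rts must not contain NA", call. = FALSE)
  base <- n %/% n_bins
  r <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, r), rep(0L, n_bins - r))
  ord <- order(rts, seq_len(n))       # stable: ties keep input order
  bins <- integer(n)
  bins[ord] <- rep(seq_len(n_bins), times = sizes)
  bins
}

#' Attach per-cell septile bins to a trial table
#'
#' Adds a `bin` column computed by [bin_septiles()] within each
#' participant-by-condition cell (over all trials of that cell, correct and
#' errors alike, unless `correct_only`).
#'
#' @param trials QC'd trial table.
#' @param n_bins Number of bins.
#' @param correct_only Bin only correct trials (used for delta plots).
#' @return The table (filtered to correct trials if `correct_only`) with a
#'   `bin` column; cells with fewer trials than bins are dropped with a
#'   warning naming the participants.
#' @export
attach_bins <- function(trials, n_bins = 7L, correct_only = FALSE) {
  if (correct_only) trials <- dplyr::filter(trials, .data$correct)
  sizes <- trials |>
    dplyr::count(.data$participant_id, .data$condition)
  small <- dplyr::filter(sizes, .data$n < n_bins)
  if (nrow(small) > 0L) {
    drop_ids <- unique(small$participant_id)
    warning("dropping participant(s) with a condition cell below ",
            n_bins, " trials: ", paste(drop_ids, collapse = ", "),
            call. = FALSE)
    trials <- dplyr::filter(trials, !.data$participant_id %in% drop_ids)
  }
  if (nrow(trials) == 0L) {
    return(dplyr::mutate(trials, bin = integer(0)))
  }
  trials |>
    dplyr::group_by(.data$participant_id, .data$condition) |>
    dplyr::mutate(bin = bin_septiles(.data$rt_ms, n_bins)) |>
    dplyr::ungroup()
}

#' Conditional accuracy functions over the RT distribution
#'
#' For each participant and condition, all trials (correct and errors) are
#' split into `n_bins` equal-count RT bins and per-bin accuracy and mean RT
#' are computed; group-level curves are the unweighted mean over
#' participants (vincentized), with the standard error of that mean.
#'
#' @param trials QC'd trial table with `participant_id`, `group`,
#'   `condition`, `rt_ms`, `correct`.
#' @param n_bins Number of bins (default 7).
#' @return A list of class `caf_result`: `by_participant` (accuracy and
#'   mean RT per participant x condition x bin) and `by_group` (mean
#'   accuracy/RT and SEMs per group x condition x bin).
#' @examples
#' cfg <- study_config(n_participants = c(young = 3, middle_aged = 3))
#' qc <- apply_exclusions(simulate_session(cfg))
#' caf <- compute_caf(qc$trials)
#' head(caf$by_group)
#' @export
compute_caf <- function(trials, n_bins = 7L) {
  binned <- attach_bins(trials, n_bins, correct_only = FALSE)
  by_participant <- binned |>
    dplyr::group_by(.data$participant_id, .data$group, .data$condition,
                    .data$bin) |>
    dplyr::summarise(accuracy = mean(.data$correct),
                     mean_rt_ms = mean(.data$rt_ms),
                     n = dplyr::n(), .groups = "drop")
  by_group <- by_participant |>
    dplyr::group_by(.data$group, .data$condition, .data$bin) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                     sem_accuracy = sem(.data$accuracy),
                     mean_rt_ms = mean(.data$mean_rt_ms),
                     sem_rt_ms = sem(.data$mean_rt_ms),
                     n_participants = dplyr::n(), .groups = "drop")
  structure(list(by_participant = by_participant, by_group = by_group,
                 n_bins = n_bins),
            class = "caf_result")
}

#' Delta plot: congruence effect on correct RTs across the distribution
#'
#' Correct trials are binned per participant within each condition; the
#' per-bin delta is the incongruent minus congruent mean RT and the
#' abscissa (midpoint) is the average of the two condition bin means.
#'
#' @inheritParams compute_caf
#' @return A list of class `delta_result`: `by_participant` (per
#'   participant x bin: `delta_ms`, `midpoint_ms` and the two condition
#'   means) and `by_group` (group mean delta/midpoint with SEMs).
#' @export
compute_delta <- function(trials, n_bins = 7L) {
  binned <- attach_bins(trials, n_bins, correct_only = TRUE)
  cell_means <- binned |>
    dplyr::group_by(.data$participant_id, .data$group, .data$condition,
                    .data$bin) |>
    dplyr::summarise(mean_rt_ms = mean(.data$rt_ms), .groups = "drop")
  by_participant <- cell_means |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = "mean_rt_ms") |>
    dplyr::filter(!is.na(.data$congruent), !is.na(.data$incongruent)) |>
    dplyr::mutate(delta_ms = .data$incongruent - .data$congruent,
                  midpoint_ms = (.data$incongruent + .data$congruent) / 2)
  by_group <- by_participant |>
    dplyr::group_by(.data$group, .data$bin) |>
    dplyr::summarise(mean_delta_ms = mean(.data$delta_ms),
                     sem_delta_ms = sem(.data$delta_ms),
                     mean_midpoint_ms = mean(.data$midpoint_ms),
                     sem_midpoint_ms = sem(.data$midpoint_ms),
                     n_participants = dplyr::n(), .groups = "drop")
  structure(list(by_participant = by_participant, by_group = by_group,
                 n_bins = n_bins),
            class = "delta_result")
}

#' Inter-bin slopes of the delta plot
#'
#' Computes, per participant, the slope of each delta-plot segment:
#' `(delta[j+1] - delta[j]) / (midpoint[j+1] - midpoint[j])`
#' (dimensionless, ms per ms). The final segment -- the conventional index
#' of selective inhibition strength -- is flagged. Setting
#' `drop_first_segment` discards segment 1, yielding a 5-level slope factor
#' from 7 bins.
#'
#' @param delta A `delta_result` from [compute_delta()].
#' @param drop_first_segment Drop the first (fastest) segment.
#' @return A list of class `slope_set`: `by_participant` (participant x
#'   segment slopes with `final_segment` flag) and `by_group` (group mean
#'   slope per segment with SEM). Segments with coincident midpoints are
#'   excluded with a warning.
#' @export
compute_slopes <- function(delta, drop_first_segment = FALSE) {
  stopifnot(inherits(delta, "delta_result"))
  if (delta$n_bins < 2L) stop("need at least 2 bins", call. = FALSE)
  seg <- delta$by_participant |>
    dplyr::arrange(.data$participant_id, .data$bin) |>
    dplyr::group_by(.data$participant_id, .data$group) |>
    dplyr::mutate(
      slope = (dplyr::lead(.data$delta_ms) - .data$delta_ms) /
        (dplyr::lead(.data$midpoint_ms) - .data$midpoint_ms),
      segment = .data$bin
    ) |>
    dplyr::filter(.data$bin < max(.data$bin)) |>
    dplyr::ungroup() |>
    dplyr::select("participant_id", "group", "segment", "slope")
  bad <- !is.finite(seg$slope)
  if (any(bad)) {
    warning(sum(bad), " segment(s) with coincident midpoints excluded",
            call. = FALSE)
    seg <- seg[!bad, , drop = FALSE]
  }
  n_seg <- max(seg$segment)
  if (drop_first_segment) seg <- dplyr::filter(seg, .data$segment > 1L)
  seg <- dplyr::mutate(seg, final_segment = .data$segment == n_seg)
  by_group <- seg |>
    dplyr::group_by(.data$group, .data$segment, .data$final_segment) |>
    dplyr::summarise(mean_slope = mean(.data$slope),
                     sem_slope = sem(.data$slope),
                     n_participants = dplyr::n(), .groups = "drop")
  structure(list(by_participant = seg, by_group = by_group),
            class = "slope_set")
}

#' Mean congruence effect on correct reaction times
#'
#' Per participant, the mean correct incongruent RT minus the mean correct
#' congruent RT, on raw milliseconds and on natural-log RTs; group level is
#' the unweighted participant mean.
#'
#' @param trials QC'd trial table.
#' @return A list of class `ce_result` with `by_participant` and
#'   `by_group` tibbles (`effect_ms`, `effect_log` plus SEMs at group
#'   level).
#' @examples
#' cfg <- study_config(n_participants = c(young = 3, middle_aged = 3))
#' qc <- apply_exclusions(simulate_session(cfg))
#' congruence_effect(qc$trials)$by_group
#' @export
congruence_effect <- function(trials) {
  correct <- dplyr::filter(trials, .data$correct)
  counts <- correct |>
    dplyr::count(.data$participant_id, .data$condition) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "n",
                       values_fill = 0L)
  if (!all(c("congruent", "incongruent") %in% names(counts)) ||
      any(counts$congruent == 0L) || any(counts$incongruent == 0L)) {
    stop("every participant needs at least one correct trial per condition",
         call. = FALSE)
  }
  by_participant <- correct |>
    dplyr::group_by(.data$participant_id, .data$group, .data$condition) |>
    dplyr::summarise(mean_rt = mean(.data$rt_ms),
                     mean_log_rt = mean(log(.data$rt_ms)),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("mean_rt", "mean_log_rt")) |>
    dplyr::mutate(
      effect_ms = .data$mean_rt_incongruent - .data$mean_rt_congruent,
      effect_log = .data$mean_log_rt_incongruent -
        .data$mean_log_rt_congruent
    ) |>
    dplyr::select("participant_id", "group", "effect_ms", "effect_log")
  by_group <- by_participant |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_effect_ms = mean(.data$effect_ms),
                     sem_effect_ms = sem(.data$effect_ms),
                     mean_effect_log = mean(.data$effect_log),
                     sem_effect_log = sem(.data$effect_log),
                     n_participants = dplyr::n(), .groups = "drop")
  structure(list(by_participant = by_participant, by_group = by_group),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<congruence effect (correct trials)>\n")
  print(x$by_group)
  invisible(x)
}

#' @export
print.caf_result <- function(x, ...) {
  cat(sprintf("<conditional accuracy functions, %d bins>\n", x$n_bins))
  print(x$by_group)
  invisible(x)
}

#' @export
print.delta_result <- function(x, ...) {
  cat(sprintf("<delta plot, %d bins>\n", x$n_bins))
  print(x$by_group)
  invisible(x)
}

#' @export
print.slope_set <- function(x, ...) {
  cat("<delta-plot segment slopes>\n")
  print(x$by_group)
  invisible(x)
}

#' @method tidy caf_result
#' @export
tidy.caf_result <- function(x, ...) x$by_group
#' @method tidy delta_result
#' @export
tidy.delta_result <- function(x, ...) x$by_group
#' @method tidy slope_set
#' @export
tidy.slope_set <- function(x, ...) x$by_group
#' @method tidy ce_result
#' @export
tidy.ce_result <- function(x, ...) x$by_group
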