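#' Quality-control configuration for trial exclusion
#'
#' Thresholds of the standard oculomotor Simon-task exclusion filters:
#' saccades under 2 degrees are fixation micromovements, latencies under
#' 100 ms are anticipations, latencies over 1000 ms outlast the target, and
#' surviving latencies more than `outlier_sd` standard deviations from the
#' mean are trimmed.
#'
#' @param min_amplitude_deg Minimum saccade amplitude kept (degrees).
#' @param min_latency_ms,max_latency_ms Latency bounds; the bounds
#'   themselves are kept (strictly-below / strictly-above removal).
#' @param outlier_sd SD multiplier of the latency trim (> 0).
#' @param outlier_scope `"per_participant"` (mean/SD per participant, both
#'   conditions pooled) or `"global"`.
#' @param outlier_on `"raw"` or `"log"` reaction times for the trim.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_amplitude_deg = 2,
                      min_latency_ms = 100,
                      max_latency_ms = 1000,
                      outlier_sd = 3,
                      outlier_scope = c("per_participant", "global"),
                      outlier_on = c("raw", "log")) {
  stopifnot(min_latency_ms < max_latency_ms, outlier_sd > 0,
            min_amplitude_deg >= 0)
  structure(
    list(min_amplitude_deg = min_amplitude_deg,
         min_latency_ms = min_latency_ms,
         max_latency_ms = max_latency_ms,
         outlier_sd = outlier_sd,
         outlier_scope = match.arg(outlier_scope),
         outlier_on = match.arg(outlier_on)),
    class = "qc_config"
  )
}

#' Apply the trial exclusion filters
#'
#' Removes, in order: (1) trials with no response; (2) saccades below the
#' amplitude floor; (3) latencies strictly below `min_latency_ms` or
#' strictly above `max_latency_ms` (the bounds themselves are valid); and
#' (4) a one-pass two-sided trim of latencies more than `outlier_sd`
#' standard deviations from the mean, where mean and SD are computed on the
#' trials surviving steps 1--3, per participant (default) or globally, with
#' both conditions pooled.
#'
#' @param trials A trial table with at least `rt_ms` and `amplitude_deg`
#'   (plus `participant_id` for the per-participant trim and `condition`
#'   for the retained-count report).
#' @param cfg A [qc_config()].
#' @return A list of class `qc_result` with elements `trials` (the retained
#'   rows, original order preserved) and `report` (a `qc_report`: per-rule
#'   and overall counts/fractions plus per-participant retained counts per
#'   condition).
#' @examples
#' cfg <- study_config(n_participants = c(young = 2, middle_aged = 2))
#' qc <- apply_exclusions(simulate_session(cfg))
#' qc$report$overall$fraction_removed
#' @export
apply_exclusions <- function(trials, cfg = qc_config()) {
  stopifnot(inherits(cfg, "qc_config"))
  need <- c("rt_ms", "amplitude_deg")
  missing <- setdiff(need, names(trials))
  if (length(missing)) {
    stop("trial table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(trials) == 0L) stop("empty trial table", call. = FALSE)

  n_in <- nrow(trials)
  alive <- rep(TRUE, n_in)
  removed_by <- rep(NA_character_, n_in)

  mark <- function(alive, bad, rule, removed_by) {
    hit <- alive & bad
    removed_by[hit] <- rule
    list(alive = alive & !hit, removed_by = removed_by)
  }

  st <- mark(alive, is.na(trials$rt_ms), "no_response", removed_by)
  st <- mark(st$alive,
             !is.na(trials$amplitude_deg) &
               trials$amplitude_deg < cfg$min_amplitude_deg,
             "amplitude", st$removed_by)
  st <- mark(st$alive,
             trials$rt_ms < cfg$min_latency_ms |
               trials$rt_ms > cfg$max_latency_ms,
             "latency", st$removed_by)

  rt <- trials$rt_ms
  if (cfg$outlier_on == "log") rt <- log(rt)
  if (cfg$outlier_scope == "per_participant") {
    if (!"participant_id" %in% names(trials)) {
      stop("per-participant outlier trim needs a participant_id column",
           call. = FALSE)
    }
    grp <- trials$participant_id
  } else {
    grp <- rep("all", n_in)
  }
  mu <- tapply(rt[st$alive], grp[st$alive], mean)
  sg <- tapply(rt[st$alive], grp[st$alive], stats::sd)
  z <- abs(rt - mu[grp]) / sg[grp]
  outlier <- !is.na(z) & z > cfg$outlier_sd
  st <- mark(st$alive, outlier, "rt_outlier", st$removed_by)

  kept <- trials[st$alive, , drop = FALSE]
  rules <- c("no_response", "amplitude", "latency", "rt_outlier")
  counts <- unname(vapply(rules,
                          function(r) sum(st$removed_by == r, na.rm = TRUE),
                          integer(1)))
  by_rule <- tibble(rule = rules, removed = counts,
                    fraction = counts / n_in)
  overall <- list(n_input = n_in, n_removed = sum(counts),
                  n_retained = n_in - sum(counts),
                  fraction_removed = sum(counts) / n_in)
  retained <- NULL
  if (all(c("participant_id", "condition") %in% names(kept))) {
    retained <- kept |>
      dplyr::count(.data$participant_id, .data$condition,
                   name = "n_retained")
  }
  report <- structure(
    list(by_rule = by_rule, overall = overall,
         retained_per_participant = retained, config = cfg),
    class = "qc_report"
  )
  structure(list(trials = as_tibble(kept), report = report),
            class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  input %d trials; removed %d (%.2f%%)\n",
              x$overall$n_input, x$overall$n_removed,
              100 * x$overall$fraction_removed))
  for (i in seq_len(nrow(x$by_rule))) {
    cat(sprintf("    %-12s %5d (%.2f%%)\n", x$by_rule$rule[i],
                x$by_rule$removed[i], 100 * x$by_rule$fraction[i]))
  }
  invisible(x)
}

#' @export
print.qc_result <- function(x, ...) {
  print(x$report)
  cat(sprintf("  retained table: %d rows\n", nrow(x$trials)))
  invisible(x)
}

#' Tidy a QC report into a per-rule tibble
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return A tibble with one row per exclusion rule plus an overall row.
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) {
  dplyr::bind_rows(
    x$by_rule,
    tibble(rule = "overall", removed = x$overall$n_removed,
           fraction = x$overall$fraction_removed)
  )
}

#' Serialise a QC report to JSON
#' @param report A `qc_report`.
#' @param path File path; the JSON is also returned invisibly.
#' @return The JSON string, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  obj <- list(
    overall = report$overall,
    by_rule = report$by_rule,
    retained_per_participant = report$retained_per_participant,
    config = unclass(report$config)
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(json)
}

#' Append natural-log reaction times
#'
#' Adds a `log_rt` column (natural log of `rt_ms`) for the mixed-model
#' stage; raw reaction times are preserved for plots and delta statistics.
#'
#' @param trials Trial table with positive `rt_ms`.
#' @return The table with a `log_rt` column appended.
#' @export
log_rts <- function(trials) {
  if (!"rt_ms" %in% names(trials)) stop("no rt_ms column", call. = FALSE)
  if (any(!is.na(trials$rt_ms) & trials$rt_ms <= 0)) {
    stop("rt_ms must be positive", call. = FALSE)
  }
  dplyr::mutate(trials, log_rt = log(.data$rt_ms))
}
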