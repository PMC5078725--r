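#' Run the full analysis pipeline
#'
#' One-call orchestration: obtain a trial table (simulate a study, read a
#' trial CSV, or detect responses from gaze traces), apply the exclusion
#' filters, compute the distributional summaries (congruence effect,
#' conditional accuracy functions, delta plot, slopes) and, optionally,
#' fit the mixed models. When `out_dir` is given, all artifacts are
#' written there: QC report JSON, CAF/delta/slope/effect CSVs, model
#' JSONs, CAF and delta figures, and a manifest recording the seed and a
#' hash of the configuration so a run can be reproduced exactly.
#'
#' @param study A [study_config()] to simulate, or `NULL` when `trials`
#'   is supplied.
#' @param trials An existing trial table (e.g. from [read_trial_csv()] or
#'   [detect_responses()]); ignored when `study` is given.
#' @param qc A [qc_config()].
#' @param n_bins RT bins for the distributional stage.
#' @param models Fit the mixed models (linear on log RT, logistic on
#'   accuracy, CAF and slope models). Skipping them keeps a run fast.
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param drop_first_segment Passed to [compute_slopes()].
#' @return A list of class `simon_report`: `trials` (retained),
#'   `qc_report`, `congruence`, `caf`, `delta`, `slopes`, `models` (NULL
#'   unless requested), `manifest`.
#' @examples
#' cfg <- study_config(n_participants = c(young = 3, middle_aged = 3),
#'                     seed = 2)
#' rep <- run_pipeline(cfg, models = FALSE)
#' rep$congruence$by_group
#' @export
run_pipeline <- function(study = NULL, trials = NULL, qc = qc_config(),
                         n_bins = 7L, models = TRUE, out_dir = NULL,
                         drop_first_segment = FALSE) {
  if (is.null(study) == is.null(trials)) {
    stop("supply exactly one input source: a study_config or a trial table",
         call. = FALSE)
  }
  seed <- NA_integer_
  if (!is.null(study)) {
    stopifnot(inherits(study, "study_config"))
    seed <- study$seed
    trials <- simulate_session(study)
  }
  res <- apply_exclusions(trials, qc)
  kept <- log_rts(res$trials)

  ce <- congruence_effect(kept)
  caf <- compute_caf(kept, n_bins)
  delta <- compute_delta(kept, n_bins)
  slopes <- compute_slopes(delta, drop_first_segment = drop_first_segment)

  fits <- NULL
  if (models) {
    multi_group <- length(unique(kept$group)) > 1L
    rt_form <- if (multi_group) log_rt ~ condition * group
               else log_rt ~ condition
    acc_form <- if (multi_group) correct ~ condition * group
                else correct ~ condition
    fits <- list(
      rt = fit_lmm(kept, rt_form),
      accuracy = fit_glmm_logit(kept, acc_form),
      caf = if (multi_group) caf_model(kept, n_bins) else NULL,
      slopes = slope_model(slopes)
    )
  }

  manifest <- list(
    seed = seed,
    n_trials_input = res$report$overall$n_input,
    n_trials_retained = res$report$overall$n_retained,
    n_bins = n_bins,
    qc = unclass(qc),
    config_hash = config_hash(list(qc = unclass(qc), n_bins = n_bins,
                                   seed = seed,
                                   study = study_signature(study))),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  report <- structure(
    list(trials = kept, qc_report = res$report, congruence = ce,
         caf = caf, delta = delta, slopes = slopes, models = fits,
         manifest = manifest),
    class = "simon_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

study_signature <- function(study) {
  if (is.null(study)) return(NULL)
  list(groups = lapply(study$groups, unclass),
       n_participants = study$n_participants,
       n_blocks = study$n_blocks, trials_per_block = study$trials_per_block,
       prop_congruent = study$prop_congruent, seed = study$seed)
}

# Small stable hash (polynomial rolling hash over the serialized config)
# for the manifest; stays inside exact double-precision integer range.
config_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  h <- 0
  for (b in as.integer(bytes)) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Write a pipeline report bundle to disk
#'
#' @param report A `simon_report` from [run_pipeline()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "simon_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_qc_report(report$qc_report, p("qc_report.json"))
  readr::write_csv(report$congruence$by_participant,
                   p("congruence_by_participant.csv"), progress = FALSE)
  readr::write_csv(report$congruence$by_group, p("congruence_by_group.csv"),
                   progress = FALSE)
  readr::write_csv(report$caf$by_group, p("caf_by_group.csv"),
                   progress = FALSE)
  readr::write_csv(report$delta$by_group, p("delta_by_group.csv"),
                   progress = FALSE)
  readr::write_csv(report$slopes$by_participant,
                   p("slopes_by_participant.csv"), progress = FALSE)
  if (!is.null(report$models)) {
    for (nm in names(report$models)) {
      if (!is.null(report$models[[nm]])) {
        write_model_json(report$models[[nm]],
                         p(sprintf("model_%s.json", nm)))
      }
    }
  }
  ggplot2::ggsave(p("caf.png"), autoplot.caf_result(report$caf),
                  width = 7, height = 4, dpi = 150)
  ggplot2::ggsave(p("delta.png"), autoplot.delta_result(report$delta),
                  width = 6, height = 4, dpi = 150)
  writeLines(jsonlite::toJSON(report$manifest, auto_unbox = TRUE,
                              digits = NA, pretty = TRUE, null = "null"),
             p("manifest.json"))
  invisible(out_dir)
}

#' @export
print.simon_report <- function(x, ...) {
  cat("<simon_report>\n")
  cat(sprintf("  %d trials retained of %d (%.2f%% removed)\n",
              x$manifest$n_trials_retained, x$manifest$n_trials_input,
              100 * x$qc_report$overall$fraction_removed))
  print(x$congruence$by_group)
  invisible(x)
}
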