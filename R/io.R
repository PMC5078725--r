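#' Read and write the trial CSV dialect
#'
#' One row per trial with header
#' `participant_id,group,block,trial,condition,rt_ms,correct,amplitude_deg,direction,route`;
#' UTF-8, `.` decimal. The `route` column (generator ground truth) is
#' optional on input. Schema violations are reported with the offending
#' column names.
#'
#' @param path File path.
#' @return `read_trial_csv()`: a tibble in trial-table form (`correct`
#'   parsed to logical).
#' @export
read_trial_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("participant_id", "group", "block", "trial", "condition",
            "rt_ms", "correct", "amplitude_deg", "direction")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("trial CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_cond <- which(!df$condition %in% c("congruent", "incongruent"))
  if (length(bad_cond)) {
    stop("invalid condition label at row(s): ",
         paste(utils::head(bad_cond, 5), collapse = ", "), call. = FALSE)
  }
  df$correct <- as.logical(df$correct)
  as_tibble(df)
}

#' @rdname read_trial_csv
#' @param trials Trial table.
#' @export
write_trial_csv <- function(trials, path) {
  readr::write_csv(trials, path, progress = FALSE)
  invisible(path)
}

#' Read and write the gaze CSV dialect
#'
#' Header `participant_id,trial,t_ms,x_deg,y_deg`; 300 Hz implied spacing,
#' screen-centre origin, degrees, rightward positive.
#'
#' @param path File path.
#' @return `read_gaze_csv()`: a tibble of gaze samples.
#' @export
read_gaze_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("participant_id", "trial", "t_ms", "x_deg", "y_deg")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("gaze CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  as_tibble(df)
}

#' @rdname read_gaze_csv
#' @param gaze Gaze sample table.
#' @export
write_gaze_csv <- function(gaze, path) {
  readr::write_csv(gaze, path, progress = FALSE)
  invisible(path)
}

#' Build a study_config from a YAML description
#'
#' The YAML mirrors [study_config()] / [group_params()]: top-level keys
#' `n_blocks`, `trials_per_block`, `prop_congruent`, `seed`, and a
#' `groups` mapping of group label to either the string
#' `"young"`/`"middle_aged"` (calibrated defaults), or a mapping of
#' `group_params` fields (unstated fields keep their defaults), plus
#' `n_participants` for the participant count.
#'
#' @param path YAML file path.
#' @return A [study_config()].
#' @export
read_study_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$groups)) stop("YAML needs a 'groups' mapping", call. = FALSE)
  groups <- list()
  n_participants <- integer()
  for (label in names(y$groups)) {
    g <- y$groups[[label]]
    n_participants[label] <- as.integer(g$n_participants %||% 10L)
    g$n_participants <- NULL
    base <- g$preset %||% NULL
    g$preset <- NULL
    gp <- if (!is.null(base)) default_group_params(base) else group_params()
    if (length(g)) gp <- do.call(update_group_params, c(list(gp), g))
    groups[[label]] <- gp
  }
  study_config(
    groups = groups,
    n_participants = n_participants,
    n_blocks = as.integer(y$n_blocks %||% 5L),
    trials_per_block = as.integer(y$trials_per_block %||% 60L),
    prop_congruent = y$prop_congruent %||% 0.5,
    seed = as.integer(y$seed %||% 1L)
  )
}
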