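#' Sample per-participant random intercepts
#'
#' Draws the latent participant intercepts of the generative model:
#' independent Normal(0, `subj_sd`^2) offsets on log controlled finishing
#' time, one per participant.
#'
#' @param gp A [group_params()] object.
#' @param n Number of participants (>= 1).
#' @param seed Integer seed; the same seed reproduces the same intercepts.
#' @param group Group label stored with each participant.
#' @return A tibble with columns `participant_id`, `group`, `intercept`.
#' @examples
#' sample_participants(group_params(subj_sd = 0.2), n = 3, seed = 1)
#' @export
sample_participants <- function(gp, n, seed = 1L, group = "group") {
  stopifnot(inherits(gp, "group_params"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  ids <- sprintf("%s_%02d", group, seq_len(n))
  b <- with_seed(derive_seed(seed, group, "intercepts"),
                 rnorm(n, 0, gp$subj_sd))
  tibble(participant_id = ids, group = group, intercept = b)
}

# Vectorised core of the dual-route race. `condition` and `location` are
# character vectors of length n; `b` a scalar or length-n intercept.
# Draw order is fixed so a given RNG state maps to a unique trial set.
race_trials <- function(n, b, gp, condition, location) {
  incong <- condition == "incongruent"

  eps <- rnorm(n, 0, gp$sigma_log_rt)
  t_ctrl_base <- exp(gp$mu_log_rt + b + eps)
  cost <- ifelse(incong,
                 pmax(0, gp$delta0 - gp$lambda_inhib *
                        pmax(0, t_ctrl_base - gp$t_ref)),
                 0)
  t_ctrl <- t_ctrl_base + cost

  launched <- runif(n) < gp$capture_prob
  t_auto <- rlnorm(n, gp$mu_log_auto, gp$sigma_log_auto)
  deadline <- rlnorm(n, gp$mu_log_suppress, gp$sigma_log_suppress)
  effective <- launched & t_auto < deadline & t_auto < t_ctrl

  lapse <- runif(n) < gp$lapse_rate

  rt <- ifelse(effective, t_auto, t_ctrl)
  correct <- ifelse(effective, !incong, !lapse)
  route <- ifelse(effective, "automatic", "controlled")

  # saccade direction actually executed: the instructed side when correct,
  # the opposite side otherwise
  instructed <- ifelse(incong, flip_side(location), location)
  direction <- ifelse(correct, instructed, flip_side(instructed))

  amplitude <- truncnorm_2deg(n)

  # contaminant kinds override the genuine race outcome
  cont <- gp$contaminants
  u <- runif(n)
  p1 <- cont$p_micro
  p2 <- p1 + cont$p_anticipatory
  p3 <- p2 + cont$p_no_response
  p4 <- p3 + cont$p_slow
  kind <- rep("genuine", n)
  kind[u < p4] <- "slow"
  kind[u < p3] <- "no_response"
  kind[u < p2] <- "anticipatory"
  kind[u < p1] <- "micro"

  u_dir <- runif(n)   # random direction for contaminant movements
  u_rt <- runif(n)    # contaminant latency draw

  is_micro <- kind == "micro"
  amplitude[is_micro] <- 0.3 + 1.6 * u_rt[is_micro]
  direction[is_micro] <- ifelse(u_dir[is_micro] < 0.5, "left", "right")
  correct[is_micro] <- direction[is_micro] == instructed[is_micro]
  route[is_micro] <- "contaminant:micro"

  is_ant <- kind == "anticipatory"
  rt[is_ant] <- 30 + 69 * u_rt[is_ant]
  direction[is_ant] <- ifelse(u_dir[is_ant] < 0.5, "left", "right")
  correct[is_ant] <- direction[is_ant] == instructed[is_ant]
  route[is_ant] <- "contaminant:anticipatory"

  is_nr <- kind == "no_response"
  rt[is_nr] <- NA_real_
  direction[is_nr] <- NA_character_
  correct[is_nr] <- NA
  amplitude[is_nr] <- NA_real_
  route[is_nr] <- "contaminant:no_response"

  is_slow <- kind == "slow"
  rt[is_slow] <- 1001 + 400 * u_rt[is_slow]
  route[is_slow] <- "contaminant:slow"

  tibble(
    condition = condition,
    rt_ms = rt,
    correct = correct,
    amplitude_deg = amplitude,
    direction = direction,
    route = route
  )
}

flip_side <- function(x) ifelse(x == "left", "right", "left")

# Normal(12, 1) saccade amplitude truncated below at the 2 degree
# micromovement boundary (rejection-free inverse-CDF draw).
truncnorm_2deg <- function(n, mean = 12, sd = 1, lower = 2) {
  plo <- pnorm(lower, mean, sd)
  stats::qnorm(plo + runif(n) * (1 - plo), mean, sd)
}

#' Simulate one trial of the dual-route race
#'
#' Runs the activation--suppression race for a single trial: a controlled
#' response whose incongruent-trial interference cost shrinks with
#' controlled finishing time, raced against an optional automatic
#' location-driven response that only takes effect if it beats both the
#' suppression deadline and the controlled response. Uses the current RNG
#' state; see [simulate_session()] for reproducible whole-session streams.
#'
#' @param participant One row of [sample_participants()] (or any list with
#'   an `intercept` field).
#' @param gp A [group_params()] object.
#' @param condition `"congruent"` or `"incongruent"`.
#' @param location Stimulus side, `"left"` or `"right"`.
#' @return A one-row tibble with `condition`, `rt_ms`, `correct`,
#'   `amplitude_deg`, `direction`, `route`.
#' @examples
#' set.seed(1)
#' p <- sample_participants(group_params(), 1)[1, ]
#' simulate_trial(p, group_params(), "incongruent")
#' @export
simulate_trial <- function(participant, gp, condition, location = "left") {
  if (!condition %in% c("congruent", "incongruent")) {
    stop("condition must be 'congruent' or 'incongruent'", call. = FALSE)
  }
  if (!location %in% c("left", "right")) {
    stop("location must be 'left' or 'right'", call. = FALSE)
  }
  race_trials(1L, participant$intercept, gp, condition, location)
}

# Balanced (condition x location) sequence for one block, shuffled in the
# caller's RNG stream. Counts are as equal as possible; with the default
# 60-trial block and 50% congruent this is 15 per 2 x 2 cell.
block_design <- function(trials_per_block, prop_congruent) {
  n_cong <- round(trials_per_block * prop_congruent)
  n_inc <- trials_per_block - n_cong
  halve <- function(k) c(ceiling(k / 2), floor(k / 2))
  cl <- halve(n_cong); il <- halve(n_inc)
  cond <- c(rep("congruent", n_cong), rep("incongruent", n_inc))
  loc <- c(rep(c("left", "right"), cl), rep(c("left", "right"), il))
  idx <- sample.int(trials_per_block)
  list(condition = cond[idx], location = loc[idx])
}

#' Simulate a full Simon-task session for each participant in a study
#'
#' Generates the complete trial table of a (possibly multi-group) study.
#' Each participant's trials come from an RNG stream keyed by the study seed
#' and the participant id, so any participant's data can be reproduced
#' without regenerating the rest. Within each block, condition and stimulus
#' side counts are balanced as in the emulated design (equal colour x
#' location cells) and the order is pseudorandom.
#'
#' @param cfg A [study_config()].
#' @return A tibble with one row per trial and columns `participant_id`,
#'   `group`, `block`, `trial`, `condition`, `rt_ms`, `correct`,
#'   `amplitude_deg`, `direction`, `route`. `route` is the generator's
#'   ground-truth label (`automatic`, `controlled`, or `contaminant:<kind>`)
#'   and is absent from real ingested data.
#' @examples
#' cfg <- study_config(n_participants = c(young = 2, middle_aged = 2),
#'                     seed = 7)
#' trials <- simulate_session(cfg)
#' dplyr::count(trials, group, condition)
#' @export
simulate_session <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  out <- vector("list", sum(cfg$n_participants))
  k <- 0L
  for (g in seq_along(cfg$group_labels)) {
    label <- cfg$group_labels[g]
    gp <- cfg$groups[[label]]
    parts <- sample_participants(gp, cfg$n_participants[g],
                                 seed = cfg$seed, group = label)
    for (i in seq_len(nrow(parts))) {
      pid <- parts$participant_id[i]
      k <- k + 1L
      out[[k]] <- with_seed(derive_seed(cfg$seed, pid), {
        blocks <- lapply(seq_len(cfg$n_blocks), function(b) {
          d <- block_design(cfg$trials_per_block, cfg$prop_congruent)
          trials <- race_trials(cfg$trials_per_block, parts$intercept[i],
                                gp, d$condition, d$location)
          trials$block <- b
          trials
        })
        ses <- dplyr::bind_rows(blocks)
        ses$trial <- seq_len(nrow(ses))
        ses$participant_id <- pid
        ses$group <- label
        ses
      })
    }
  }
  dplyr::bind_rows(out) |>
    dplyr::select("participant_id", "group", "block", "trial", "condition",
                  "rt_ms", "correct", "amplitude_deg", "direction", "route")
}
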