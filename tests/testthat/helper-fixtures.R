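# Shared fixture builders. Everything is generated in code at test time.

# A hand-specifiable trial table: rts/correct per condition, one participant.
manual_trials <- function(rt_con, rt_inc,
                          cor_con = rep(TRUE, length(rt_con)),
                          cor_inc = rep(TRUE, length(rt_inc)),
                          participant = "p01", group = "young") {
  tibble::tibble(
    participant_id = participant,
    group = group,
    block = 1L,
    trial = seq_len(length(rt_con) + length(rt_inc)),
    condition = rep(c("congruent", "incongruent"),
                    c(length(rt_con), length(rt_inc))),
    rt_ms = c(rt_con, rt_inc),
    correct = c(cor_con, cor_inc),
    amplitude_deg = 12,
    direction = "left",
    route = "controlled"
  )
}

# A quiet generator: no automatic route, no interference, no lapses, no
# contaminants -- congruent and incongruent trials are the same process.
quiet_params <- function(...) {
  group_params(
    mu_log_rt = log(300), sigma_log_rt = 0.15, subj_sd = 0.05,
    capture_prob = 0, delta0 = 0, lambda_inhib = 0, lapse_rate = 0,
    contaminants = list(p_micro = 0, p_anticipatory = 0,
                        p_no_response = 0, p_slow = 0),
    ...
  )
}

small_study <- function(n_young = 4L, n_mid = 4L, trials_per_block = 60L,
                        n_blocks = 5L, seed = 11L,
                        young = default_group_params("young"),
                        middle = default_group_params("middle_aged")) {
  study_config(
    groups = list(young = young, middle_aged = middle),
    n_participants = c(young = n_young, middle_aged = n_mid),
    n_blocks = n_blocks, trials_per_block = trials_per_block, seed = seed
  )
}

# Independent naive septile binning used as the oracle for bin_septiles():
# walks the sorted order explicitly and assigns bins from cumulative sizes.
naive_bins <- function(rts, n_bins) {
  n <- length(rts)
  sizes <- rep(n %/% n_bins, n_bins)
  if (n %% n_bins > 0) {
    sizes[seq_len(n %% n_bins)] <- sizes[seq_len(n %% n_bins)] + 1L
  }
  df <- data.frame(rt = rts, idx = seq_len(n))
  df <- df[order(df$rt, df$idx), ]
  out <- integer(n)
  pos <- 1L
  for (b in seq_len(n_bins)) {
    take <- df$idx[pos:(pos + sizes[b] - 1L)]
    out[take] <- b
    pos <- pos + sizes[b]
  }
  out
}
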