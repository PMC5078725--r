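test_that("participant intercepts have the configured spread and reproduce under a seed", {
  gp0 <- group_params(subj_sd = 0)
  p0 <- sample_participants(gp0, 5, seed = 1)
  expect_equal(p0$intercept, rep(0, 5))

  gp <- group_params(subj_sd = 0.2)
  p1 <- sample_participants(gp, 10000, seed = 2)
  expect_lt(abs(sd(p1$intercept) - 0.2) / 0.2, 0.02)

  p2 <- sample_participants(gp, 10000, seed = 2)
  expect_identical(p1, p2)
  expect_error(sample_participants(gp, 0), "positive")
})

test_that("with both routes disabled, condition label has no effect on the generated law", {
  cfg <- study_config(groups = list(g = quiet_params()),
                      n_participants = c(g = 1L),
                      n_blocks = 1L, trials_per_block = 2000L, seed = 5)
  trials <- simulate_session(cfg)
  expect_true(all(trials$correct))
  expect_true(all(trials$route == "controlled"))
  ks <- suppressWarnings(stats::ks.test(
    trials$rt_ms[trials$condition == "congruent"],
    trials$rt_ms[trials$condition == "incongruent"]
  ))
  expect_gt(ks$p.value, 0.01)
})

test_that("distributional null holds across replicate sessions", {
  # routes disabled: congruent vs incongruent RTs should be KS-compatible
  # at alpha = 0.01 in at least 98% of sessions
  pvals <- vapply(1:100, function(r) {
    cfg <- study_config(groups = list(g = quiet_params()),
                        n_participants = c(g = 1L),
                        n_blocks = 1L, trials_per_block = 300L,
                        seed = 1000L + r)
    tr <- simulate_session(cfg)
    suppressWarnings(stats::ks.test(
      tr$rt_ms[tr$condition == "congruent"],
      tr$rt_ms[tr$condition == "incongruent"]
    ))$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.98)
})

test_that("an overwhelming automatic route produces near-total fast errors with the automatic law", {
  gp <- group_params(
    mu_log_rt = log(400), sigma_log_rt = 0.10, subj_sd = 0,
    capture_prob = 1, mu_log_auto = log(120), sigma_log_auto = 0.15,
    mu_log_suppress = 14, sigma_log_suppress = 0.4,   # deadline never binds
    delta0 = 0, lambda_inhib = 0, lapse_rate = 0,
    contaminants = list(p_micro = 0, p_anticipatory = 0,
                        p_no_response = 0, p_slow = 0)
  )
  cfg <- study_config(groups = list(g = gp), n_participants = c(g = 1L),
                      n_blocks = 1L, trials_per_block = 20000L, seed = 8)
  inc <- dplyr::filter(simulate_session(cfg), condition == "incongruent")
  expect_gt(mean(!inc$correct), 0.999)
  err_log <- log(inc$rt_ms[!inc$correct])
  expect_lt(abs(mean(err_log) - log(120)), 3 * 0.15 / sqrt(length(err_log)) + 0.003)
  expect_lt(abs(sd(err_log) - 0.15), 0.01)
})

test_that("Monte-Carlo incongruent error rate matches the quadrature oracle", {
  gp <- update_group_params(default_group_params("middle_aged"),
                            subj_sd = 0,
                            contaminants = list(p_micro = 0,
                                                p_anticipatory = 0,
                                                p_no_response = 0,
                                                p_slow = 0))
  # closed-form P(error) over the three independent lognormal clocks:
  # error = effective capture, or a lapse of the surviving controlled route
  g_inv <- function(a) {
    # inverse of the interference-cost map t -> t + max(0, d0 - l*(t - t0)+)
    d0 <- gp$delta0; l <- gp$lambda_inhib; t0 <- gp$t_ref
    ifelse(a <= t0 + d0, a - d0,
           ifelse(a <= t0 + d0 / l, (a - d0 - l * t0) / (1 - l), a))
  }
  s_ctrl <- function(a) 1 - stats::plnorm(pmax(g_inv(a), 0),
                                          gp$mu_log_rt, gp$sigma_log_rt)
  integrand <- function(a) {
    stats::dlnorm(a, gp$mu_log_auto, gp$sigma_log_auto) *
      (1 - stats::plnorm(a, gp$mu_log_suppress, gp$sigma_log_suppress)) *
      s_ctrl(a)
  }
  p_eff <- gp$capture_prob *
    stats::integrate(integrand, 0, Inf, rel.tol = 1e-9)$value
  p_err <- p_eff + (1 - p_eff) * gp$lapse_rate

  n <- 2e5
  cfg <- study_config(groups = list(g = gp), n_participants = c(g = 1L),
                      n_blocks = 1L, trials_per_block = as.integer(n),
                      seed = 13)
  inc <- dplyr::filter(simulate_session(cfg), condition == "incongruent")
  mc <- mean(!inc$correct)
  se <- sqrt(p_err * (1 - p_err) / nrow(inc))
  expect_lt(abs(mc - p_err), 3 * se)
})

test_that("sessions have the full balanced design at the emulated sample sizes", {
  cfg <- study_config(n_participants = c(young = 43L, middle_aged = 39L),
                      seed = 21)
  trials <- simulate_session(cfg)
  expect_equal(nrow(trials), 82L * 300L)
  per <- dplyr::count(trials, participant_id)
  expect_true(all(per$n == 300L))
  percond <- dplyr::count(trials, participant_id, condition)
  expect_true(all(percond$n == 150L))
  # block structure: condition balance holds within every block
  perblock <- dplyr::count(trials, participant_id, block, condition)
  expect_true(all(perblock$n == 30L))
})

test_that("simulation is reproducible and participant streams are independently keyed", {
  cfg <- small_study(n_young = 3, n_mid = 2, seed = 99)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a, b)

  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(a, f1)
  write_trial_csv(b, f2)
  expect_identical(readLines(f1), readLines(f2))

  # growing the cohort leaves earlier participants' data unchanged
  cfg_big <- small_study(n_young = 5, n_mid = 2, seed = 99)
  big <- simulate_session(cfg_big)
  ids <- unique(a$participant_id[a$group == "young"])
  expect_identical(
    dplyr::filter(a, participant_id %in% ids),
    dplyr::filter(big, participant_id %in% ids)
  )
})

test_that("raising capture probability weakly lowers incongruent accuracy", {
  accs <- vapply(c(0.1, 0.4, 0.7), function(cp) {
    gp <- update_group_params(default_group_params("young"),
                              capture_prob = cp)
    cfg <- study_config(groups = list(g = gp), n_participants = c(g = 1L),
                        n_blocks = 1L, trials_per_block = 30000L, seed = 3)
    inc <- dplyr::filter(simulate_session(cfg), condition == "incongruent")
    mean(inc$correct, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(accs) < 0))
})

test_that("single-trial simulation validates labels and honours route semantics", {
  p <- sample_participants(quiet_params(), 1)[1, ]
  expect_error(simulate_trial(p, quiet_params(), "neutral"), "condition")
  set.seed(4)
  tr <- simulate_trial(p, quiet_params(), "incongruent", location = "right")
  expect_true(tr$correct)
  expect_identical(tr$direction, "left")  # instructed side opposes location
})
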