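test_that("zero between-participant variance reduces the LMM to ordinary least squares", {
  dat <- make_lmm_data(10, 30, subj_sd = 0, seed = 3,
                       center_participants = TRUE)
  fit <- fit_lmm(dat, log_rt ~ condition * group)
  expect_lt(fit$ranef_sd^2, 1e-6)
  ols <- stats::lm(log_rt ~ condition * group, data = prep_for_lm(dat))
  expect_equal(fit$fixed$estimate, unname(stats::coef(ols)),
               tolerance = 1e-6)
  expect_true(any(grepl("singular", fit$notes)))
})

test_that("LMM fixed effects match a direct REML optimizer on small instances", {
  dat <- make_lmm_data(8, 12, subj_sd = 0.2, seed = 7)   # 96 rows
  fit <- fit_lmm(dat, log_rt ~ condition + group)
  pf <- prep_for_lm(dat)
  X <- stats::model.matrix(~ condition + group, pf)
  oracle <- reml_oracle(dat$log_rt, X, dat$participant_id)
  expect_equal(fit$fixed$estimate, unname(oracle$beta), tolerance = 1e-4)
  expect_equal(fit$ranef_sd, sqrt(oracle$tau2), tolerance = 1e-3)
})

test_that("single-df Wald statistics equal the squared z ratio", {
  dat <- make_lmm_data(8, 20, seed = 11)
  fit <- fit_lmm(dat, log_rt ~ condition)
  est <- fit$fixed$estimate[fit$fixed$term == "conditionincongruent"]
  se <- fit$fixed$std_error[fit$fixed$term == "conditionincongruent"]
  wald <- dplyr::filter(fit$tests, test == "Wald chi-square",
                        term == "condition")
  expect_equal(wald$statistic, (est / se)^2, tolerance = 1e-8)
})

test_that("the ML likelihood at the mixed optimum dominates the null-variance model", {
  dat <- make_lmm_data(8, 20, subj_sd = 0.1, seed = 13)
  fit <- fit_lmm(dat, log_rt ~ condition, reml = FALSE)
  ols <- stats::lm(log_rt ~ condition, data = prep_for_lm(dat))
  expect_gte(as.numeric(stats::logLik(fit$fit)),
             as.numeric(stats::logLik(ols)) - 1e-6)
})

test_that("LMM recovers a known congruence coefficient across replicates", {
  hits <- vapply(1:50, function(r) {
    dat <- make_lmm_data(12, 40, beta_cond = 0.05, subj_sd = 0.15,
                         seed = 100 + r)
    fit <- fit_lmm(dat, log_rt ~ condition + group)
    i <- fit$fixed$term == "conditionincongruent"
    abs(fit$fixed$estimate[i] - 0.05) <= 3 * fit$fixed$std_error[i]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the interaction F test holds its nominal type-I error under the null", {
  pvals <- vapply(1:200, function(r) {
    dat <- make_lmm_data(10, 24, beta_int = 0, seed = 2000 + r)
    fit <- fit_lmm(dat, log_rt ~ condition * group)
    dplyr::filter(fit$tests, test == "Wald chi-square",
                  term == "condition:group")$p_value
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  # binomial 99% envelope around 0.05 at 200 replicates
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.10)
})

test_that("zero-variance data reduce the logistic mixed model to plain logistic regression", {
  dat <- make_glmm_data(10, 40, subj_sd = 0, seed = 17)
  fit <- fit_glmm_logit(dat, correct ~ condition)
  glm_fit <- stats::glm(correct ~ condition, data = prep_for_lm(dat),
                        family = stats::binomial())
  expect_equal(fit$fixed$estimate, unname(stats::coef(glm_fit)),
               tolerance = 1e-3)
})

test_that("GLMM fixed effects match a direct quadrature optimizer on small instances", {
  dat <- make_glmm_data(12, 16, beta0 = 1.5, beta_cond = -0.8,
                        subj_sd = 0.5, seed = 19)
  fit <- fit_glmm_logit(dat, correct ~ condition, nagq = 25)
  pf <- prep_for_lm(dat)
  X <- stats::model.matrix(~ condition, pf)
  oracle <- glmm_oracle(as.numeric(dat$correct), X, dat$participant_id)
  expect_equal(fit$fixed$estimate, unname(oracle$beta), tolerance = 1e-3)
})

test_that("GLMM recovery of known accuracy coefficients across replicates", {
  hits <- vapply(1:25, function(r) {
    dat <- make_glmm_data(20, 60, beta0 = 2.2, beta_cond = -1,
                          subj_sd = 0.5, seed = 300 + r)
    fit <- fit_glmm_logit(dat, correct ~ condition)
    i <- fit$fixed$term == "conditionincongruent"
    abs(fit$fixed$estimate[i] - (-1)) <= 3 * fit$fixed$std_error[i]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("adaptive quadrature is converged in the node count", {
  dat <- make_glmm_data(15, 30, seed = 23)
  f7 <- fit_glmm_logit(dat, correct ~ condition, nagq = 7)
  f31 <- fit_glmm_logit(dat, correct ~ condition, nagq = 31)
  expect_lt(max(abs(f7$fixed$estimate - f31$fixed$estimate)), 1e-3)
})

test_that("complete separation is detected, flagged and fitted finitely", {
  dat <- make_glmm_data(8, 30, seed = 29)
  dat$correct[dat$condition == "congruent"] <- TRUE   # separated cell
  fit <- fit_glmm_logit(dat, correct ~ condition)
  expect_true(any(grepl("separation", fit$notes)))
  expect_true(all(is.finite(fit$fixed$estimate)))
  expect_true(all(abs(fit$fixed$estimate) < 20))
})

test_that("the CAF model runs the 2 x 2 x 7 analysis and extracts the first-bin contrast", {
  cfg <- small_study(n_young = 6, n_mid = 6, seed = 37)
  res <- apply_exclusions(simulate_session(cfg))
  fit <- caf_model(res$trials)
  terms <- dplyr::filter(fit$tests, test == "Wald chi-square")$term
  expect_true(all(c("condition", "group", "bin", "condition:group",
                    "condition:group:bin") %in% terms))
  expect_s3_class(fit$first_bin, "model_fit")
  expect_true("groupmiddle_aged" %in% fit$first_bin$fixed$term)
})

test_that("a single RT bin degrades the CAF model to condition x group with a warning", {
  cfg <- small_study(n_young = 3, n_mid = 3, n_blocks = 1L,
                     trials_per_block = 40L, seed = 41)
  res <- apply_exclusions(simulate_session(cfg))
  tr <- dplyr::mutate(res$trials, bin = 1L)
  expect_warning(fit <- caf_model(tr), "single RT bin")
  terms <- dplyr::filter(fit$tests, test == "Wald chi-square")$term
  expect_false("bin" %in% terms)
})

test_that("the slope model tests group and segment effects and the final segment separately", {
  cfg <- small_study(n_young = 8, n_mid = 8, seed = 43)
  res <- apply_exclusions(simulate_session(cfg))
  slopes <- compute_slopes(compute_delta(res$trials))
  fit <- slope_model(slopes)
  terms <- dplyr::filter(fit$tests, test == "Wald chi-square")$term
  expect_true(all(c("segment", "group") %in% terms))
  expect_false(is.null(fit$final_segment))
  expect_true(is.finite(fit$final_segment$p_value))
})

test_that("constant slopes yield an exactly null group effect", {
  slopes <- structure(list(
    by_participant = tibble::tibble(
      participant_id = rep(sprintf("p%02d", 1:8), each = 3),
      group = rep(c("young", "middle_aged"), each = 12),
      segment = rep(1:3, 8),
      slope = -0.1,
      final_segment = rep(c(FALSE, FALSE, TRUE), 8)
    ),
    by_group = NULL), class = "slope_set")
  fit <- suppressWarnings(suppressMessages(slope_model(slopes)))
  i <- grepl("^group", fit$fixed$term)
  expect_equal(fit$fixed$estimate[i], 0, tolerance = 1e-10)
  expect_equal(fit$final_segment$estimate, 0, tolerance = 1e-10)
})

test_that("overall R-squared approaches one on noiseless responses", {
  dat <- make_lmm_data(8, 20, subj_sd = 0.3, sigma = 1e-4, seed = 47)
  fit <- fit_lmm(dat, log_rt ~ condition + group)
  expect_gt(fit$r2, 0.999)
})

test_that("tidy and glance expose estimates, tests and fit summaries", {
  dat <- make_lmm_data(6, 20, seed = 53)
  fit <- fit_lmm(dat, log_rt ~ condition)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_true(all(c("term", "estimate", "std_error") %in%
                    names(tidy(fit))))
  expect_true("p_value" %in% names(tidy(fit, effects = "tests")))
  g <- glance(fit)
  expect_equal(nrow(g), 1L)
  expect_true(g$r_squared >= 0 && g$r_squared <= 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  expect_true(jsonlite::validate(paste(readLines(path), collapse = "\n")))
})
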