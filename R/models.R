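#' Fitted random-intercept mixed model with per-term tests
#'
#' Internal constructor for the `model_fit` class returned by
#' [fit_lmm()], [fit_glmm_logit()], [caf_model()] and [slope_model()].
#' Carries fixed-effect estimates/SEs, the random-intercept SD, per-term
#' test statistics, the overall R-squared (squared Pearson correlation of
#' fitted and observed responses) and convergence notes.
#' @noRd
new_model_fit <- function(fit, fixed, ranef_sd, tests, r2, family,
                          notes = character()) {
  structure(
    list(fit = fit, fixed = fixed, ranef_sd = ranef_sd, tests = tests,
         r2 = r2, family = family, notes = notes),
    class = "model_fit"
  )
}

fixed_table <- function(fit) {
  co <- summary(fit)$coefficients
  tibble(term = rownames(co), estimate = unname(co[, "Estimate"]),
         std_error = unname(co[, "Std. Error"]))
}

wald_tests <- function(fit) {
  a <- car::Anova(fit, type = "II")
  tibble(term = rownames(a), statistic = unname(a[, "Chisq"]),
         df = unname(a[, "Df"]), p_value = unname(a[, "Pr(>Chisq)"]),
         test = "Wald chi-square")
}

r2_fitted <- function(fit, response) {
  stats::cor(stats::fitted(fit), response)^2
}

#' Linear mixed model on log reaction times
#'
#' Fits a random-intercept linear mixed model by REML:
#' `response ~ fixed terms + (1 | participant_id)`. Primary per-term tests
#' are Wald chi-square statistics (always well defined); F tests with
#' Satterthwaite denominator degrees of freedom are reported alongside.
#' Factors use treatment coding with the reference levels congruent /
#' young / bin 1 / segment 1 where those columns are present.
#'
#' @param trials Data frame with the response, the fixed-effect columns
#'   and `participant_id`; at least two participants.
#' @param fixed One-sided or two-sided formula giving response and fixed
#'   terms, e.g. `log_rt ~ condition * group`.
#' @param reml Use REML (default) or ML.
#' @return A `model_fit`: fixed-effect tibble, random-intercept SD,
#'   residual SD, per-term Wald and F tests, overall R-squared, and the
#'   underlying `lmerMod` in `$fit`. Access tidily via [tidy.model_fit()]
#'   and [glance.model_fit()].
#' @examples
#' cfg <- study_config(n_participants = c(young = 4, middle_aged = 4))
#' qc <- apply_exclusions(simulate_session(cfg))
#' fit <- fit_lmm(log_rts(qc$trials), log_rt ~ condition * group)
#' glance(fit)
#' @export
fit_lmm <- function(trials, fixed = log_rt ~ condition * group,
                    reml = TRUE) {
  trials <- prep_factors(trials)
  check_participants(trials)
  f <- add_random(fixed)
  fit <- lmerTest::lmer(f, data = trials, REML = reml)
  response <- stats::model.frame(fit)[[1L]]
  vc <- as.data.frame(lme4::VarCorr(fit))
  ranef_sd <- vc$sdcor[vc$grp == "participant_id"][1]
  ftab <- tryCatch({
    a <- stats::anova(fit, type = 2)
    tibble(term = rownames(a), statistic = unname(a[, "F value"]),
           df = unname(a[, "NumDF"]), df_denom = unname(a[, "DenDF"]),
           p_value = unname(a[, "Pr(>F)"]), test = "F (Satterthwaite)")
  }, error = function(e) NULL)
  tests <- dplyr::bind_rows(wald_tests(fit), ftab)
  notes <- character()
  if (lme4::isSingular(fit)) notes <- c(notes, "singular fit (variance at boundary)")
  new_model_fit(fit, fixed_table(fit), ranef_sd, tests,
                r2_fitted(fit, response), family = "gaussian", notes = notes)
}

#' Logistic mixed model on trial-level accuracy
#'
#' Fits a random-intercept logistic (Bernoulli) mixed model by maximum
#' likelihood with adaptive Gauss--Hermite quadrature over the participant
#' intercept. Per-term tests are Wald chi-square statistics. Complete
#' separation (a fixed-effect cell whose outcomes are all identical, which
#' sends estimates unbounded) is detected; the model is then refitted with
#' a light data-augmentation ridge (one success and one failure per
#' design cell at small weight) and flagged in `$notes`.
#'
#' @param trials Data frame with a logical/0-1 response, fixed-effect
#'   columns, `participant_id`.
#' @param fixed Formula, e.g. `correct ~ condition * group`.
#' @param nagq Number of adaptive quadrature nodes (default 15).
#' @return A `model_fit` (see [fit_lmm()]); `$fit` is a `glmerMod`.
#' @export
fit_glmm_logit <- function(trials, fixed = correct ~ condition * group,
                           nagq = 15L) {
  trials <- prep_factors(trials)
  check_participants(trials)
  f <- add_random(fixed)
  resp_name <- all.vars(fixed)[1]
  trials[[resp_name]] <- as.numeric(trials[[resp_name]])
  notes <- character()

  sep <- detect_separation(trials, fixed)
  wts <- rep(1, nrow(trials))
  dat <- trials
  if (sep$separated) {
    notes <- c(notes, paste0("complete separation in cell(s): ",
                             paste(sep$cells, collapse = "; "),
                             "; fitted with data-augmentation ridge"))
    dat <- dplyr::bind_rows(trials, sep$augment)
    wts <- c(rep(1, nrow(trials)), rep(0.05, nrow(sep$augment)))
  }
  dat$`..w` <- wts
  ws <- character()
  fit <- withCallingHandlers(
    lme4::glmer(f, data = dat, family = stats::binomial(), nAGQ = nagq,
                weights = `..w`),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (!grepl("non-integer", msg)) ws <<- c(ws, msg)
      invokeRestart("muffleWarning")
    }
  )
  notes <- c(notes, ws)
  response <- trials[[resp_name]]
  fitted_obs <- stats::fitted(fit)[seq_len(nrow(trials))]
  vc <- as.data.frame(lme4::VarCorr(fit))
  ranef_sd <- vc$sdcor[vc$grp == "participant_id"][1]
  new_model_fit(fit, fixed_table(fit), ranef_sd, wald_tests(fit),
                stats::cor(fitted_obs, response)^2, family = "binomial",
                notes = notes)
}

# Flag fixed-effect design cells whose binary outcomes are all identical,
# and build the matching augmentation rows (one 0 and one 1 per cell).
detect_separation <- function(trials, fixed) {
  resp <- all.vars(fixed)[1]
  terms <- all.vars(fixed)[-1]
  terms <- intersect(terms, names(trials))
  if (!length(terms)) return(list(separated = FALSE))
  cells <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(terms))) |>
    dplyr::summarise(all_same = length(unique(.data[[resp]])) == 1L,
                     .groups = "drop")
  bad <- dplyr::filter(cells, .data$all_same)
  if (nrow(bad) == 0L) return(list(separated = FALSE))
  augment <- bad |>
    dplyr::select(-"all_same") |>
    dplyr::slice(rep(seq_len(nrow(bad)), each = 2L)) |>
    dplyr::mutate(!!resp := rep(c(0, 1), nrow(bad)),
                  participant_id = trials$participant_id[1])
  labels <- apply(dplyr::select(bad, -"all_same"), 1L, paste,
                  collapse = "/")
  list(separated = TRUE, cells = labels, augment = augment)
}

prep_factors <- function(trials) {
  relevel_if <- function(x, ref) {
    x <- factor(x)
    if (ref %in% levels(x)) stats::relevel(x, ref) else x
  }
  if ("condition" %in% names(trials)) {
    trials$condition <- relevel_if(trials$condition, "congruent")
  }
  if ("group" %in% names(trials)) {
    trials$group <- relevel_if(trials$group, "young")
  }
  for (col in c("bin", "segment")) {
    if (col %in% names(trials)) {
      trials[[col]] <- relevel_if(trials[[col]],
                                  as.character(min(as.integer(
                                    as.character(factor(trials[[col]])))))
      )
    }
  }
  trials
}

check_participants <- function(trials) {
  if (!"participant_id" %in% names(trials)) {
    stop("participant_id column required", call. = FALSE)
  }
  if (length(unique(trials$participant_id)) < 2L) {
    stop("need at least two participants", call. = FALSE)
  }
  invisible(trials)
}

add_random <- function(fixed) {
  stats::update.formula(fixed, . ~ . + (1 | participant_id))
}

#' Conditional-accuracy mixed model over congruence, group and bin
#'
#' Attaches septile bins and fits the trial-level logistic mixed model
#' `correct ~ condition * group * bin + (1 | participant_id)` (a
#' 2 x 2 x 7 analysis by default). If the data hold a single bin the model
#' degenerates to `condition * group` with a warning. A convenience
#' first-bin contrast -- the group effect on incongruent accuracy within
#' bin 1, the conventional index of automatic activation strength -- is
#' attached as `$first_bin`.
#'
#' @param trials QC'd trial table (bins are attached internally via
#'   [attach_bins()] when no `bin` column is present).
#' @param n_bins Number of RT bins (default 7).
#' @param nagq Quadrature nodes for the logistic fits.
#' @return A `model_fit` with an extra `$first_bin` element (itself a
#'   `model_fit`, or `NULL` when a group column is absent).
#' @export
caf_model <- function(trials, n_bins = 7L, nagq = 15L) {
  if (!"bin" %in% names(trials)) {
    trials <- attach_bins(trials, n_bins, correct_only = FALSE)
  }
  one_bin <- length(unique(trials$bin)) < 2L
  form <- if (one_bin) {
    warning("single RT bin: falling back to condition x group model",
            call. = FALSE)
    correct ~ condition * group
  } else {
    correct ~ condition * group * bin
  }
  fit <- fit_glmm_logit(trials, form, nagq = nagq)
  first_bin <- NULL
  if (!one_bin && "group" %in% names(trials) &&
      length(unique(trials$group)) > 1L) {
    sub <- dplyr::filter(trials, .data$bin == 1L,
                         .data$condition == "incongruent")
    first_bin <- fit_glmm_logit(sub, correct ~ group, nagq = nagq)
  }
  fit$first_bin <- first_bin
  fit
}

#' Mixed model on delta-plot slopes
#'
#' Fits `slope ~ segment + group + (1 | participant_id)` on the
#' per-participant segment slopes (a 2 x k slope-position analysis) and,
#' separately, the group contrast restricted to the final segment -- the
#' conventional focus for selective-inhibition strength. With one slope
#' value per participant the final-segment contrast is an ordinary linear
#' model F test.
#'
#' @param slopes A `slope_set` from [compute_slopes()].
#' @param interaction Include the segment-by-group interaction.
#' @return A `model_fit` with an extra `$final_segment` element holding
#'   `estimate` (group difference), `statistic`, `df`, `p_value` of the
#'   final-segment group contrast (or `NULL` with a single group).
#' @export
slope_model <- function(slopes, interaction = FALSE) {
  stopifnot(inherits(slopes, "slope_set"))
  dat <- slopes$by_participant
  form <- if (interaction) slope ~ segment * group else slope ~ segment + group
  if (length(unique(dat$group)) < 2L) {
    form <- stats::update.formula(form, . ~ segment)
  }
  fit <- fit_lmm(dat, form)
  final <- NULL
  if (length(unique(dat$group)) > 1L) {
    fin <- dplyr::filter(dat, .data$final_segment)
    lmfit <- stats::lm(slope ~ group, data = prep_factors(fin))
    a <- stats::anova(lmfit)
    final <- list(
      estimate = unname(stats::coef(lmfit)[2]),
      statistic = a[1, "F value"],
      df = c(a[1, "Df"], a[2, "Df"]),
      p_value = a[1, "Pr(>F)"],
      test = "F (final segment, between participants)"
    )
  }
  fit$final_segment <- final
  fit
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit: %s random-intercept model>\n", x$family))
  cat(sprintf("  participant intercept SD %.4f; overall R^2 %.3f\n",
              x$ranef_sd, x$r2))
  print(as.data.frame(x$tests), digits = 4)
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Tidy fixed effects or tests of a fitted mixed model
#'
#' @param x A `model_fit`.
#' @param effects `"fixed"` (estimates and SEs) or `"tests"` (per-term
#'   Wald chi-square and, for linear models, Satterthwaite F tests).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy model_fit
#' @export
tidy.model_fit <- function(x, effects = c("fixed", "tests"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") x$fixed else x$tests
}

#' One-row model summary
#'
#' @param x A `model_fit`.
#' @param ... Unused.
#' @return A tibble with the family, random-intercept SD, log-likelihood,
#'   overall R-squared and number of observations.
#' @method glance model_fit
#' @export
glance.model_fit <- function(x, ...) {
  tibble(family = x$family,
         ranef_sd = x$ranef_sd,
         log_lik = as.numeric(stats::logLik(x$fit)),
         r_squared = x$r2,
         nobs = stats::nobs(x$fit),
         notes = paste(x$notes, collapse = "; "))
}

#' Serialise a model fit to JSON
#'
#' @param x A `model_fit`.
#' @param path Output path.
#' @return The JSON string, invisibly.
#' @export
write_model_json <- function(x, path) {
  stopifnot(inherits(x, "model_fit"))
  obj <- list(family = x$family, fixed = x$fixed, ranef_sd = x$ranef_sd,
              tests = x$tests, r2 = x$r2, notes = x$notes)
  if (!is.null(x$final_segment)) obj$final_segment <- x$final_segment
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(json)
}
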