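trial_row <- function(rt_ms = 250, amplitude_deg = 12, direction = "right",
                      participant_id = "p01", trial = 1L) {
  tibble::tibble(participant_id = participant_id, trial = trial,
                 rt_ms = rt_ms, amplitude_deg = amplitude_deg,
                 direction = direction)
}

test_that("velocity estimation is exact on constant and linear traces", {
  n <- 200
  t_ms <- seq(0, by = 1000 / 300, length.out = n)
  flat <- structure(list(t_ms = t_ms, x_deg = rep(1.5, n),
                         y_deg = rep(0, n), stimulus_onset_ms = 0,
                         true_onset_ms = NA_real_,
                         participant_id = "p", trial = 1L),
                    class = "gaze_trace")
  expect_equal(estimate_velocity(flat), rep(0, n))

  ramp <- flat
  ramp$x_deg <- 10 * t_ms / 1000  # 10 deg/s
  v <- estimate_velocity(ramp)
  expect_equal(v[5:(n - 5)], rep(10, n - 9), tolerance = 1e-9)
})

test_that("programmed peak velocity is recovered within 10% at default noise", {
  set.seed(2)
  tr <- trial_row(rt_ms = 300, amplitude_deg = 12)
  g <- synthesize_gaze_trace(tr)
  v <- estimate_velocity(g)
  # minimum-jerk peak velocity = 1.875 * A / T with the main-sequence T
  t_dur <- (21 + 2.2 * 12) / 1000
  pk_true <- 1.875 * 12 / t_dur
  expect_lt(abs(max(abs(v)) - pk_true) / pk_true, 0.10)
})

test_that("a noiseless displacement lands on target and detection finds one event", {
  set.seed(3)
  tr <- trial_row(rt_ms = 250, amplitude_deg = 12, direction = "right")
  g0 <- synthesize_gaze_trace(tr, noise_sd_deg = 0)
  expect_lt(abs(utils::tail(g0$x_deg, 1) - 12), 0.1)

  ev <- detect_saccades(g0)
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$amplitude_deg - 12), 0.5)
  expect_identical(ev$direction, "right")
  # noiseless onset error at most one sample (3.33 ms)
  expect_lte(abs(ev$onset_ms - g0$true_onset_ms), 1000 / 300 + 1e-9)

  tr_nr <- trial_row(rt_ms = NA_real_, amplitude_deg = NA_real_,
                     direction = NA_character_)
  g_nr <- synthesize_gaze_trace(tr_nr)
  expect_equal(nrow(detect_saccades(g_nr)), 0L)
})

test_that("flat noisy fixation yields no events", {
  set.seed(4)
  tr_nr <- trial_row(rt_ms = NA_real_, amplitude_deg = NA_real_,
                     direction = NA_character_)
  g <- synthesize_gaze_trace(tr_nr, noise_sd_deg = 0.1)
  expect_equal(nrow(detect_saccades(g)), 0L)
})

test_that("a microsaccade and a full saccade straddle the 2-degree response cutoff", {
  set.seed(5)
  micro <- synthesize_gaze_trace(trial_row(rt_ms = 180, amplitude_deg = 1),
                                 noise_sd_deg = 0.02)
  full <- synthesize_gaze_trace(trial_row(rt_ms = 260, amplitude_deg = 12),
                                noise_sd_deg = 0.02)
  combined <- micro
  combined$x_deg <- micro$x_deg + full$x_deg
  ev <- detect_saccades(combined)
  expect_equal(nrow(ev), 2L)
  expect_lt(min(ev$amplitude_deg), 2)
  expect_gt(max(ev$amplitude_deg), 2)

  resp <- extract_response(ev, combined)
  expect_equal(resp$rt_ms, 260, tolerance = 2 * 1000 / 300)
  expect_gt(resp$amplitude_deg, 2)
})

test_that("response extraction skips micromovements and handles empty event sets", {
  tr <- trial_row()
  g <- synthesize_gaze_trace(tr, noise_sd_deg = 0)
  empty <- tibble::tibble(onset_ms = numeric(), offset_ms = numeric(),
                          amplitude_deg = numeric(), direction = character(),
                          peak_velocity = numeric())
  expect_null(extract_response(empty, g))

  ev <- tibble::tibble(onset_ms = c(680, 760), offset_ms = c(700, 800),
                       amplitude_deg = c(1.5, 12),
                       direction = c("left", "right"),
                       peak_velocity = c(50, 400))
  resp <- extract_response(ev, g)   # stimulus onset at 500 ms
  expect_equal(resp$rt_ms, 260)
  expect_identical(resp$direction, "right")
})

test_that("detection is antisymmetric under horizontal mirroring", {
  set.seed(6)
  g <- synthesize_gaze_trace(trial_row(rt_ms = 240, amplitude_deg = 10,
                                       direction = "right"))
  g_flip <- g
  g_flip$x_deg <- -g$x_deg
  ev <- detect_saccades(g)
  ev_flip <- detect_saccades(g_flip)
  expect_equal(nrow(ev), nrow(ev_flip))
  expect_equal(ev$onset_ms, ev_flip$onset_ms)
  expect_equal(ev$amplitude_deg, ev_flip$amplitude_deg)
  expect_identical(ev_flip$direction,
                   ifelse(ev$direction == "right", "left", "right"))
})

test_that("onset recovery stays within one sample for nearly all default-noise traces", {
  set.seed(7)
  n_tr <- 300
  hits <- logical(n_tr)
  for (i in seq_len(n_tr)) {
    rt <- stats::runif(1, 150, 600)
    g <- synthesize_gaze_trace(trial_row(rt_ms = rt, amplitude_deg = 12,
                                         direction = sample(c("left", "right"), 1)))
    ev <- detect_saccades(g)
    resp <- extract_response(ev, g)
    hits[i] <- !is.null(resp) &&
      abs((resp$rt_ms + g$stimulus_onset_ms) - g$true_onset_ms) <=
      1000 / 300 + 1e-9
  }
  expect_gte(mean(hits), 0.95)
})

test_that("detected responses reproduce generator ground truth end to end", {
  cfg <- study_config(n_participants = c(young = 2, middle_aged = 1),
                      n_blocks = 1L, trials_per_block = 60L, seed = 23)
  trials <- simulate_session(cfg)
  set.seed(8)
  traces <- purrr::map(seq_len(nrow(trials)),
                       function(i) synthesize_gaze_trace(trials[i, ]))
  detected <- detect_responses(traces)
  merged <- dplyr::inner_join(
    trials, detected, by = c("participant_id", "trial"),
    suffix = c("_true", "_det")
  )
  genuine <- dplyr::filter(merged, route %in% c("automatic", "controlled"))
  ok <- with(genuine, direction_det == direction_true &
               abs(rt_ms_det - rt_ms_true) <= 2 * 1000 / 300)
  expect_gte(mean(ok), 0.99)
  # no-response contaminants must yield no detected response
  nr <- dplyr::filter(merged, route == "contaminant:no_response")
  if (nrow(nr) > 0) expect_true(all(is.na(nr$rt_ms_det)))
})

test_that("gaze tables round-trip through the CSV dialect", {
  set.seed(9)
  g <- synthesize_gaze_trace(trial_row())
  tab <- gaze_to_table(g)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gaze_csv(tab, path)
  back <- read_gaze_csv(path)
  expect_equal(back$x_deg, tab$x_deg, tolerance = 1e-9)
  g2 <- gaze_from_table(back, stimulus_onset_ms = 500)
  ev1 <- detect_saccades(g)
  ev2 <- detect_saccades(g2)
  expect_equal(ev1$onset_ms, ev2$onset_ms)
})
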