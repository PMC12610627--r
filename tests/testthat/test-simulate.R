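test_that("latent trajectory honours the zero-noise and determinism contracts", {
  p0 <- simulate_latent_trajectory(6, difficulty = 0, seed = 1, step_sd = 0)
  expect_equal(p0$trust, rep(0.8, 6))
  expect_true(all(diff(p0$t_task_s) > 0))

  a <- simulate_latent_trajectory(8, 0.4, seed = 99)
  b <- simulate_latent_trajectory(8, 0.4, seed = 99)
  expect_identical(a, b)
  expect_true(all(a$trust >= 0 & a$trust <= 1))
  expect_error(simulate_latent_trajectory(0, 0.5, 1), class = "trustfuse_invalid_argument")
})

test_that("harder scenarios produce lower mean latent trust", {
  means <- function(diff) {
    vapply(
      1:200,
      function(s) mean(simulate_latent_trajectory(8, diff, seed = s)$trust),
      numeric(1)
    )
  }
  tt <- t.test(means(0.9), means(0.1))
  expect_lt(tt$p.value, 0.01)
  expect_lt(tt$estimate[1], tt$estimate[2])
})

test_that("EEG simulation emits the requested sample count and timeline", {
  prof <- simulate_latent_trajectory(8, 0.5, seed = 2)
  sim <- simulate_eeg_recording(prof, fs = 500, seed = 3, rest_s = 10, task_s = 60)
  expect_identical(nrow(sim$recording), 35000L)
  expect_equal(nrow(sim$events), 8)
  expect_true(all(sim$events$t_start_s > 10))
  expect_error(
    simulate_eeg_recording(prof[0, ], seed = 1),
    class = "trustfuse_invalid_argument"
  )
})

test_that("the alpha/beta ratio separates high from low latent trust", {
  silent <- artifact_config(
    emg_burst_rate = 0, emg_amplitude = 0,
    motion_rate = 0, motion_amplitude = 0, noise_sd = 0
  )
  prof_hi <- tibble::tibble(event_index = 1:4, t_task_s = c(2, 6.5, 11, 15.5), trust = rep(1, 4))
  prof_lo <- dplyr::mutate(prof_hi, trust = 0)
  hi <- simulate_eeg_recording(prof_hi, silent, seed = 4)
  lo <- simulate_eeg_recording(prof_lo, silent, seed = 4)
  r_hi <- epoch_band_powers(preprocess_eeg(hi$recording), hi$events)$ratio
  r_lo <- epoch_band_powers(preprocess_eeg(lo$recording), lo$events)$ratio
  expect_true(all(r_hi > r_lo))
})

test_that("EMG bursts inflate the dispersion of epoch ratios", {
  silent <- artifact_config(
    emg_burst_rate = 0, emg_amplitude = 0,
    motion_rate = 0, motion_amplitude = 0, noise_sd = 1
  )
  bursty <- artifact_config(
    emg_burst_rate = 20, emg_amplitude = 30,
    motion_rate = 0, motion_amplitude = 0, noise_sd = 1
  )
  vr <- vapply(1:5, function(s) {
    prof <- simulate_latent_trajectory(8, 0.5, seed = s)
    a <- simulate_eeg_recording(prof, silent, seed = s + 10)
    b <- simulate_eeg_recording(prof, bursty, seed = s + 10)
    c(
      var(epoch_band_powers(preprocess_eeg(a$recording), a$events)$ratio),
      var(epoch_band_powers(preprocess_eeg(b$recording), b$events)$ratio)
    )
  }, numeric(2))
  expect_gt(mean(vr[2, ]), mean(vr[1, ]))
})

test_that("questionnaire generation saturates, reverse-keys and rounds as documented", {
  r1 <- simulate_questionnaire(1, bias = 0, noise_sd = 0, seed = 1)
  expect_true(all(as.numeric(r1[sprintf("item%02d", 4:12)]) == 10))
  expect_true(all(as.numeric(r1[sprintf("item%02d", 1:3)]) == 1))

  # round-half-up: 1 + 9 * 0.5 = 5.5 discretizes to 6
  r2 <- simulate_questionnaire(0.5, bias = 0, noise_sd = 0, seed = 1)
  expect_true(all(as.numeric(r2[sprintf("item%02d", 4:12)]) == 6))
  expect_true(all(as.numeric(r2[sprintf("item%02d", 1:3)]) == 5))
})

test_that("positive social-desirability bias inflates the scored questionnaire mean", {
  sc <- function(bias) {
    mean(vapply(1:200, function(s) {
      score_questionnaire(
        simulate_questionnaire(0.4, bias = bias, noise_sd = 0.6, seed = s)
      )$score
    }, numeric(1)))
  }
  expect_gt(sc(0.3), sc(0))
})

test_that("behavioral coding recovers the latent extremes and the latent ordering", {
  top <- simulate_behavior(1, noise_sd = 0, seed = 1)
  expect_equal(top$adherence_pct, 100)
  expect_equal(top$latency_s, 0)
  expect_equal(score_behavior(top)$score, 10)

  bottom <- simulate_behavior(0, noise_sd = 0, seed = 1)
  expect_equal(score_behavior(bottom)$score, 0)

  set.seed(31)
  u <- runif(500)
  scores <- vapply(seq_along(u), function(i) {
    score_behavior(simulate_behavior(u[i], noise_sd = 0.05, seed = i))$score
  }, numeric(1))
  expect_gt(cor(u, scores, method = "spearman"), 0.9)
})

test_that("cohort generation is deterministic down to the serialized bytes", {
  cfg <- cohort_config(n_participants = 2, events_per_scenario = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(config = cfg, seed = 123), d1)
  write_cohort(simulate_cohort(config = cfg, seed = 123), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(
      unname(tools::md5sum(file.path(d1, f))),
      unname(tools::md5sum(file.path(d2, f))),
      info = f
    )
  }
  expect_error(simulate_cohort(1, cfg, seed = 1), class = "trustfuse_invalid_argument")
})

test_that("the default cohort matches the study layout", {
  cfg <- cohort_config()
  expect_equal(cfg$n_participants, 21)
  expect_equal(nrow(cfg$scenarios), 3)
  co <- simulate_cohort(n_participants = 3, config = cfg, seed = 5)
  expect_equal(nrow(co$events), 3 * 3 * cfg$events_per_scenario)
  expect_setequal(unique(co$events$scenario), cfg$scenarios$scenario_id)
  # every questionnaire / behavior record references a timeline event
  expect_true(all(co$questionnaire$event_id %in% co$events$event_id))
  expect_true(all(co$behavior$event_id %in% co$events$event_id))
})

test_that("bias distorts the questionnaire but never the behavioral scores", {
  cfg0 <- cohort_config(
    n_participants = 2, events_per_scenario = 3,
    questionnaire = list(bias_mean = 0, bias_sd = 0, noise_sd = 0.6)
  )
  cfg1 <- cohort_config(
    n_participants = 2, events_per_scenario = 3,
    questionnaire = list(bias_mean = 0.3, bias_sd = 0, noise_sd = 0.6)
  )
  c0 <- simulate_cohort(config = cfg0, seed = 11)
  c1 <- simulate_cohort(config = cfg1, seed = 11)
  expect_gt(
    mean(score_questionnaire(c1$questionnaire)$score),
    mean(score_questionnaire(c0$questionnaire)$score)
  )
  expect_identical(c0$behavior, c1$behavior)
})
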