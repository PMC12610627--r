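#' Artifact model configuration for synthetic EEG
#'
#' Controls the contamination injected into simulated task EEG: EMG-like
#' band-limited bursts (20-45 Hz noise under a 200 ms Tukey envelope),
#' motion-like low-frequency transients (sub-2 Hz half-sine pulses), and a
#' 1/f background. All rates are per minute of task time, amplitudes in µV.
#'
#' @param emg_burst_rate EMG bursts per minute.
#' @param emg_band EMG carrier band in Hz.
#' @param emg_amplitude EMG burst amplitude (µV, RMS of the carrier).
#' @param motion_rate Motion transients per minute.
#' @param motion_amplitude Motion transient peak amplitude (µV).
#' @param noise_sd Standard deviation of the 1/f background (µV).
#'
#' @return A list of class `artifact_config`.
#' @export
artifact_config <- function(emg_burst_rate = 4, emg_band = c(20, 45),
                            emg_amplitude = 20, motion_rate = 2,
                            motion_amplitude = 30, noise_sd = 1.5) {
  vals <- c(emg_burst_rate, emg_amplitude, motion_rate, motion_amplitude, noise_sd)
  if (any(vals < 0)) {
    stop_invalid("Artifact rates and amplitudes must be >= 0.", "trustfuse_invalid_argument")
  }
  structure(
    list(
      emg_burst_rate = emg_burst_rate, emg_band = emg_band,
      emg_amplitude = emg_amplitude, motion_rate = motion_rate,
      motion_amplitude = motion_amplitude, noise_sd = noise_sd
    ),
    class = "artifact_config"
  )
}

#' Simulate a latent trust trajectory over a session's decision points
#'
#' Latent trust is modelled as a session level set by task difficulty plus a
#' smooth, session-centred Ornstein-Uhlenbeck fluctuation, reflected into
#' \[0, 1\]. The fluctuation is centred within the session so that the session
#' mean is controlled by difficulty alone, which keeps per-session
#' standardized EEG scores comparable across sessions. Higher difficulty
#' lowers mean trust (`level = 0.8 - 0.5 * difficulty`).
#'
#' @param n_events Number of decision points (>= 1).
#' @param difficulty Scenario difficulty in \[0, 1\].
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @param step_sd Innovation standard deviation of the fluctuation.
#' @param reversion Mean-reversion rate in (0, 1\]; higher is less smooth.
#' @param first_event_s,event_spacing_s Decision-point schedule in seconds
#'   from task onset.
#'
#' @return A tibble with columns `event_index`, `t_task_s` (strictly
#'   increasing) and `trust` in \[0, 1\]; attributes `difficulty` and `seed`.
#' @export
#' @examples
#' simulate_latent_trajectory(8, difficulty = 0.5, seed = 1)
simulate_latent_trajectory <- function(n_events, difficulty, seed,
                                       step_sd = 0.11, reversion = 0.3,
                                       first_event_s = 2, event_spacing_s = 4.5) {
  if (!is.numeric(n_events) || n_events < 1) {
    stop_invalid("`n_events` must be >= 1.", "trustfuse_invalid_argument")
  }
  assert_scalar_in(difficulty, 0, 1, "difficulty")
  n_events <- as.integer(n_events)
  level <- 0.8 - 0.5 * difficulty
  w <- with_seed(seed, {
    eps <- rnorm(n_events, 0, step_sd)
    out <- numeric(n_events)
    for (k in seq_len(n_events)[-1]) {
      out[k] <- (1 - reversion) * out[k - 1] + eps[k]
    }
    out
  })
  traj <- level + (w - mean(w))
  # reflect into [0, 1]
  traj <- abs(traj %% 2)
  traj <- ifelse(traj > 1, 2 - traj, traj)
  tibble::tibble(
    event_index = seq_len(n_events),
    t_task_s = first_event_s + event_spacing_s * (seq_len(n_events) - 1),
    trust = traj
  ) |>
    structure(difficulty = difficulty, seed = seed)
}

# 1/f ("pink") background noise with unit sd, via spectral shaping.
pink_noise <- function(n) {
  wh <- rnorm(n)
  sp <- fft(wh)
  f <- c(1, seq_len(n - 1)) # avoid dividing DC by zero
  f <- pmin(f, n - f + 1) # two-sided symmetric frequency index
  sp <- sp / sqrt(f)
  x <- Re(fft(sp, inverse = TRUE)) / n
  x / sd(x)
}

# Tukey (tapered cosine) window, alpha = taper fraction.
tukey_window <- function(n, alpha = 0.5) {
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}

#' Simulate a single-channel EEG recording from a latent trust profile
#'
#' Generates a 10 s resting-state prefix followed by the task signal. The
#' task EEG is a two-oscillator mixture: a 10 Hz alpha component whose
#' amplitude increases with latent trust and a 20 Hz beta component whose
#' amplitude decreases with it (so the alpha/beta power ratio is strictly
#' increasing in trust and the true ordering is recoverable), plus a 1/f
#' background and Poisson-scheduled EMG bursts and motion transients from
#' `artifacts`. Decision points are emitted as an event timeline.
#'
#' @param profile Latent trajectory from [simulate_latent_trajectory()].
#' @param artifacts An [artifact_config()].
#' @param fs Sampling rate in Hz (>= 100).
#' @param seed Integer seed.
#' @param rest_s Resting baseline duration (s).
#' @param task_s Task duration (s); default extends 4.5 s past the last
#'   decision point.
#' @param participant_id,scenario_id Identifiers attached to the recording.
#'
#' @return A list with elements `recording` (a `trustfuse_eeg` tibble) and
#'   `events` (tibble `event_id`, `t_start_s`, `label`, `scenario`).
#' @export
simulate_eeg_recording <- function(profile, artifacts = artifact_config(),
                                   fs = 500, seed = 1, rest_s = 10,
                                   task_s = NULL,
                                   participant_id = "P01",
                                   scenario_id = "scenario") {
  if (nrow(profile) < 1L) {
    stop_invalid("`profile` must contain at least one event.", "trustfuse_invalid_argument")
  }
  if (fs < 100) {
    stop_invalid("`fs` must be >= 100 Hz.", "trustfuse_invalid_argument")
  }
  if (is.null(task_s)) task_s <- max(profile$t_task_s) + 4.5
  n <- as.integer(round((rest_s + task_s) * fs))
  t <- (seq_len(n) - 1) / fs
  task <- t >= rest_s

  # latent trust sampled at every time point: neutral during rest; during
  # the task each time point takes the trust level of the nearest decision
  # point, so an epoch cut around an event reflects exactly that event's
  # latent state
  u <- rep(0.5, n)
  ev_t <- profile$t_task_s + rest_s
  mid <- head(ev_t, -1) + diff(ev_t) / 2
  u[task] <- profile$trust[findInterval(t[task], mid) + 1L]

  x <- with_seed(seed, {
    ph <- runif(2, 0, 2 * pi)
    # alpha power rises and beta power falls with latent trust, calibrated
    # so the alpha/beta power ratio is linear in trust (0.5 + 2u): linearity
    # keeps per-session z-scores on a common footing across sessions
    beta_pow <- 18 - 8 * u
    alpha_pow <- (0.5 + 2 * u) * beta_pow
    sig <- sqrt(2 * alpha_pow) * sin(2 * pi * 10 * t + ph[1]) +
      sqrt(2 * beta_pow) * sin(2 * pi * 20 * t + ph[2])
    if (artifacts$noise_sd > 0) {
      sig <- sig + artifacts$noise_sd * pink_noise(n)
    }
    # EMG bursts: band-limited carrier (sum of random tones in emg_band)
    # under a 200 ms Tukey envelope, task segment only
    n_bursts <- rpois(1, artifacts$emg_burst_rate * task_s / 60)
    if (n_bursts > 0 && artifacts$emg_amplitude > 0) {
      dur <- as.integer(round(0.2 * fs))
      env <- tukey_window(dur, 0.5)
      centers <- runif(n_bursts, rest_s, rest_s + task_s - 0.25)
      for (ct in centers) {
        i0 <- as.integer(round(ct * fs)) + 1L
        idx <- i0:(i0 + dur - 1L)
        idx <- idx[idx <= n]
        freqs <- runif(8, artifacts$emg_band[1], artifacts$emg_band[2])
        phs <- runif(8, 0, 2 * pi)
        tb <- t[idx]
        carrier <- rowSums(vapply(
          seq_len(8),
          function(j) sin(2 * pi * freqs[j] * tb + phs[j]), numeric(length(idx))
        ))
        carrier <- carrier / sqrt(mean(carrier^2))
        sig[idx] <- sig[idx] + artifacts$emg_amplitude * carrier * env[seq_along(idx)]
      }
    }
    # motion transients: sub-2 Hz half-sine pulses
    n_mot <- rpois(1, artifacts$motion_rate * task_s / 60)
    if (n_mot > 0 && artifacts$motion_amplitude > 0) {
      dur <- as.integer(round(0.8 * fs))
      centers <- runif(n_mot, rest_s, rest_s + task_s - 0.85)
      signs <- sample(c(-1, 1), n_mot, replace = TRUE)
      for (j in seq_len(n_mot)) {
        i0 <- as.integer(round(centers[j] * fs)) + 1L
        idx <- i0:(i0 + dur - 1L)
        idx <- idx[idx <= n]
        pulse <- sin(pi * seq_along(idx) / dur)
        sig[idx] <- sig[idx] + signs[j] * artifacts$motion_amplitude * pulse
      }
    }
    sig
  })

  rec <- eeg_recording(
    tibble::tibble(time_s = t, eeg_uV = x),
    fs = fs, rest_end_s = rest_s,
    participant_id = participant_id, scenario_id = scenario_id
  )
  events <- tibble::tibble(
    event_id = sprintf("%s_%s_E%02d", participant_id, scenario_id, profile$event_index),
    t_start_s = profile$t_task_s + rest_s,
    label = sprintf("decision_%02d", profile$event_index),
    scenario = scenario_id
  )
  list(recording = rec, events = events)
}

#' Simulate one questionnaire response
#'
#' Each of the 12 Likert items is generated as
#' `clip(round(1 + 9 * (latent + bias) + N(0, noise_sd)), 1, 10)` with
#' round-half-up discretization. Items 1-3 are distrust-phrased and are
#' stored inverted (`11 - value`), so the raw response sheet carries the
#' questionnaire's mixed keying; [score_questionnaire()] undoes it.
#'
#' @param latent Latent trust in \[0, 1\].
#' @param bias Social-desirability bias in \[-1, 1\] (additive on the latent
#'   scale; positive inflates self-report).
#' @param noise_sd Response noise on the 1-10 scale.
#' @param seed Integer seed.
#' @param participant_id,event_id Identifiers.
#'
#' @return A one-row tibble: `participant`, `event_id`, `item01`..`item12`.
#' @export
#' @examples
#' simulate_questionnaire(1, bias = 0, noise_sd = 0, seed = 1)
simulate_questionnaire <- function(latent, bias = 0, noise_sd = 0, seed = 1,
                                   participant_id = "P01", event_id = "E01") {
  assert_scalar_in(latent, 0, 1, "latent")
  assert_scalar_in(bias, -1, 1, "bias")
  keyed <- with_seed(seed, {
    raw <- 1 + 9 * (latent + bias) + rnorm(12, 0, noise_sd)
    clip(round_half_up(raw), 1, 10)
  })
  vals <- keyed
  vals[reverse_keyed_items()] <- 11 - keyed[reverse_keyed_items()]
  out <- tibble::tibble(participant = participant_id, event_id = event_id)
  out[sprintf("item%02d", 1:12)] <- as.list(as.integer(vals))
  out
}

#' Simulate one behavioral coding record
#'
#' Generates the five observational indicators monotonically in latent trust
#' with optional noise, such that [score_behavior()] with default norms
#' recovers approximately `10 * latent`: full adherence, zero latency and
#' zero counts at `latent = 1`; degraded adherence, long latency and
#' frequent interventions as latent trust falls.
#'
#' @inheritParams simulate_questionnaire
#' @param noise_sd Noise on the latent scale applied independently per
#'   indicator.
#' @param norms Scaling constants, see [behavior_norms()].
#'
#' @return One-row tibble: `participant`, `event_id`, `adherence_pct`,
#'   `latency_s`, `reliance`, `interventions`, `verifications`, `coder_id`.
#' @export
simulate_behavior <- function(latent, noise_sd = 0, seed = 1,
                              norms = behavior_norms(),
                              participant_id = "P01", event_id = "E01",
                              coder_id = "C1") {
  assert_scalar_in(latent, 0, 1, "latent")
  with_seed(seed, {
    eff <- clip(latent + rnorm(5, 0, noise_sd), 0, 1)
    count_from <- function(u) {
      if (u <= 0) Inf else round_half_up(norms$c * (1 / u - 1))
    }
    tibble::tibble(
      participant = participant_id,
      event_id = event_id,
      adherence_pct = 100 * eff[1],
      latency_s = if (eff[2] <= 0) Inf else -norms$tau * log(eff[2]),
      reliance = count_from(eff[3]),
      interventions = count_from(eff[4]),
      verifications = count_from(eff[5]),
      coder_id = coder_id
    )
  })
}

#' Default configuration for the synthetic cohort generator
#'
#' Returns the generator parameters emulating the study conditions: 21
#' participants, three scenarios of graded difficulty with 8 decision points
#' each, 500 Hz EEG with a 10 s resting baseline, EMG/motion contamination
#' on, and a positive social-desirability bias on the questionnaire.
#' Any component can be overridden by passing a replacement.
#'
#' @param n_participants Cohort size.
#' @param scenarios Tibble with `scenario_id` and `difficulty` columns.
#' @param events_per_scenario Decision points per scenario.
#' @param fs,rest_s EEG sampling rate (Hz) and resting baseline (s).
#' @param latent Latent-trajectory dynamics (`step_sd`, `reversion`).
#' @param artifacts An [artifact_config()].
#' @param questionnaire Questionnaire generation (`bias_mean`, `bias_sd`,
#'   `noise_sd`); the bias is drawn once per participant.
#' @param behavior Behavioral generation (`noise_sd` on the latent scale).
#' @param norms Behavioral scoring constants, see [behavior_norms()].
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 21,
                          scenarios = tibble::tibble(
                            scenario_id = c("cane_walker", "stairs", "handrail"),
                            difficulty = c(0.3, 0.7, 0.5)
                          ),
                          events_per_scenario = 8,
                          fs = 500, rest_s = 10,
                          latent = list(step_sd = 0.11, reversion = 0.3),
                          artifacts = artifact_config(),
                          questionnaire = list(bias_mean = 0.3, bias_sd = 0.08, noise_sd = 0.6),
                          behavior = list(noise_sd = 0.05),
                          norms = behavior_norms()) {
  structure(
    list(
      n_participants = n_participants, scenarios = scenarios,
      events_per_scenario = events_per_scenario, fs = fs, rest_s = rest_s,
      latent = latent, artifacts = artifacts, questionnaire = questionnaire,
      behavior = behavior, norms = norms
    ),
    class = "cohort_config"
  )
}

#' A noise-free cohort configuration
#'
#' Convenience wrapper for recoverability analyses: all artifacts, biases
#' and noise terms disabled, and a common scenario difficulty so that
#' between-session level differences do not mask within-session dynamics.
#'
#' @inheritParams cohort_config
#' @export
cohort_config_clean <- function(n_participants = 21, events_per_scenario = 8) {
  cohort_config(
    n_participants = n_participants,
    scenarios = tibble::tibble(
      scenario_id = c("cane_walker", "stairs", "handrail"),
      difficulty = c(0.5, 0.5, 0.5)
    ),
    events_per_scenario = events_per_scenario,
    # wider latent excursions so the trajectory spans the trust scale,
    # separating Likert levels and exercising the whole score range
    latent = list(step_sd = 0.22, reversion = 0.3),
    artifacts = artifact_config(
      emg_burst_rate = 0, emg_amplitude = 0,
      motion_rate = 0, motion_amplitude = 0, noise_sd = 0
    ),
    questionnaire = list(bias_mean = 0, bias_sd = 0, noise_sd = 0),
    behavior = list(noise_sd = 0)
  )
}

#' Simulate a complete synthetic cohort
#'
#' Generates, per participant and scenario: a latent trust trajectory, a
#' contaminated EEG recording with its event timeline, one questionnaire
#' response per decision point, and one behavioral coding per decision
#' point. Every random draw descends deterministically from `seed` through
#' named substreams, so identical seeds give identical cohorts.
#'
#' @param n_participants Number of participants (>= 2).
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#'
#' @return A list of class `trust_cohort`: `recordings` (named list of
#'   `trustfuse_eeg`), `events`, `questionnaire`, `behavior`, `latent`
#'   (tibbles keyed by `participant`, `scenario`, `event_id`), plus `seed`
#'   and `config`.
#' @export
simulate_cohort <- function(n_participants = NULL, config = cohort_config(),
                            seed = 1) {
  if (is.null(n_participants)) n_participants <- config$n_participants
  if (n_participants < 2) {
    stop_invalid("`n_participants` must be >= 2.", "trustfuse_invalid_argument")
  }
  pids <- sprintf("P%02d", seq_len(n_participants))
  recordings <- list()
  events <- list()
  quests <- list()
  behavs <- list()
  latents <- list()
  for (pi in seq_along(pids)) {
    pid <- pids[pi]
    bias <- with_seed(
      derive_seed(seed, "bias", pid),
      clip(rnorm(1, config$questionnaire$bias_mean, config$questionnaire$bias_sd), -1, 1)
    )
    for (si in seq_len(nrow(config$scenarios))) {
      scen <- config$scenarios$scenario_id[si]
      diff <- config$scenarios$difficulty[si]
      prof <- simulate_latent_trajectory(
        config$events_per_scenario, diff,
        seed = derive_seed(seed, "latent", pid, scen),
        step_sd = config$latent$step_sd, reversion = config$latent$reversion
      )
      sim <- simulate_eeg_recording(
        prof, config$artifacts,
        fs = config$fs,
        seed = derive_seed(seed, "eeg", pid, scen),
        rest_s = config$rest_s, participant_id = pid, scenario_id = scen
      )
      key <- paste(pid, scen, sep = "_")
      recordings[[key]] <- sim$recording
      events[[key]] <- dplyr::mutate(sim$events, participant = pid, .before = 1)
      latents[[key]] <- tibble::tibble(
        participant = pid, scenario = scen,
        event_id = sim$events$event_id,
        t_start_s = sim$events$t_start_s,
        trust = prof$trust
      )
      qrows <- purrr::map2_dfr(prof$trust, sim$events$event_id, function(u, eid) {
        simulate_questionnaire(u, bias, config$questionnaire$noise_sd,
          seed = derive_seed(seed, "quest", eid),
          participant_id = pid, event_id = eid
        )
      })
      brows <- purrr::map2_dfr(prof$trust, sim$events$event_id, function(u, eid) {
        simulate_behavior(u, config$behavior$noise_sd,
          seed = derive_seed(seed, "behav", eid),
          norms = config$norms,
          participant_id = pid, event_id = eid
        )
      })
      quests[[key]] <- dplyr::mutate(qrows, scenario = scen, .after = 1)
      behavs[[key]] <- dplyr::mutate(brows, scenario = scen, .after = 1)
    }
  }
  structure(
    list(
      recordings = recordings,
      events = dplyr::bind_rows(events),
      questionnaire = dplyr::bind_rows(quests),
      behavior = dplyr::bind_rows(behavs),
      latent = dplyr::bind_rows(latents),
      seed = seed,
      config = config
    ),
    class = "trust_cohort"
  )
}

#' @export
print.trust_cohort <- function(x, ...) {
  cat(sprintf(
    "<trust_cohort> %d participants x %d scenarios, %d events, seed %d\n",
    length(unique(x$events$participant)),
    nrow(x$config$scenarios), nrow(x$events), x$seed
  ))
  invisible(x)
}
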