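# Independent oracles used across the suite. Each deliberately re-derives
# its quantity from first principles (definitions, exhaustive enumeration),
# never by calling the implementation under test.

# Single Hann-tapered periodogram straight from the DFT (one-sided density).
oracle_hann_periodogram <- function(x, fs) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
  sp <- stats::fft(x * w)[seq_len(n %/% 2 + 1)]
  p <- Mod(sp)^2 / (fs * sum(w^2))
  dbl <- rep(2, length(p))
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[length(p)] <- 1
  data.frame(freq = (seq_along(p) - 1) * fs / n, psd = p * dbl)
}

# Kruskal-Wallis H from the definition: rank everything, compare group rank
# sums, apply the tie correction.
oracle_kruskal_h <- function(x, g) {
  g <- as.factor(g)
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) * sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Cohen's kappa by brute-force marginal computation from the label pairs.
oracle_kappa <- function(a, b) {
  lev <- sort(unique(c(as.character(a), as.character(b))))
  n <- length(a)
  po <- mean(as.character(a) == as.character(b))
  pe <- sum(vapply(lev, function(l) {
    mean(as.character(a) == l) * mean(as.character(b) == l)
  }, numeric(1)))
  (po - pe) / (1 - pe)
}

# Kendall tau-b by exhaustive O(n^2) pair counting with tie corrections.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[i] - x[j]
      dy <- y[i] - y[j]
      if (dx == 0 && dy == 0) next
      if (dx == 0) {
        tx <- tx + 1
      } else if (dy == 0) {
        ty <- ty + 1
      } else if (sign(dx) == sign(dy)) {
        conc <- conc + 1
      } else {
        disc <- disc + 1
      }
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# Cronbach's alpha via the covariance matrix: k/(k-1) * (1 - tr(C)/sum(C)).
oracle_cronbach <- function(m) {
  cmat <- stats::cov(m)
  k <- ncol(m)
  k / (k - 1) * (1 - sum(diag(cmat)) / sum(cmat))
}

# A fixed "planted" ANFIS used by the recovery tests.
planted_anfis <- function() {
  trustfuse:::new_anfis(
    centers = matrix(c(3.25, 7.75, 3.0, 8.0), 2, 2,
      byrow = TRUE,
      dimnames = list(c("eeg", "questionnaire"), c("Low", "High"))
    ),
    widths = matrix(2.25, 2, 2,
      dimnames = list(c("eeg", "questionnaire"), c("Low", "High"))
    ),
    consequents = matrix(
      c(
        0.5, 0.2, 1.0,
        0.3, 0.6, 0.5,
        0.7, 0.1, 2.0,
        0.4, 0.5, 1.5
      ), 4, 3,
      byrow = TRUE, dimnames = list(NULL, c("a", "b", "d"))
    )
  )
}

# Training triples drawn from the planted model (3 events per participant).
planted_triples <- function(n_participants = 21, noise_sd = 0, seed = 42) {
  set.seed(seed)
  n <- 3 * n_participants
  d <- tibble::tibble(
    participant = rep(sprintf("P%02d", seq_len(n_participants)), each = 3),
    eeg = runif(n, 1, 10),
    questionnaire = runif(n, 1, 10)
  )
  d$behavior <- anfis_forward(planted_anfis(), d$eeg, d$questionnaire) +
    rnorm(n, 0, noise_sd)
  d
}

# Pooled per-event score table for a cohort: EEG, questionnaire, behavior
# (and optionally fused) against the latent trajectory.
cohort_score_table <- function(cohort, fuse = FALSE, epochs = 100) {
  curves <- purrr::imap_dfr(cohort$recordings, function(rec, key) {
    ev <- dplyr::filter(
      cohort$events,
      .data$participant == attr(rec, "participant_id"),
      .data$scenario == attr(rec, "scenario_id")
    )
    compute_trust_curve(rec, ev)
  })
  tab <- cohort$latent |>
    dplyr::select("participant", "scenario", "event_id", "trust") |>
    dplyr::inner_join(
      dplyr::select(curves, "event_id", eeg = "score"),
      by = "event_id"
    ) |>
    dplyr::inner_join(
      dplyr::select(score_questionnaire(cohort$questionnaire),
        "event_id",
        questionnaire = "score"
      ),
      by = "event_id"
    ) |>
    dplyr::inner_join(
      dplyr::select(score_behavior(cohort$behavior), "event_id", behavior = "score"),
      by = "event_id"
    )
  if (fuse) {
    fit <- anfis_fit(tab, epochs = epochs)
    tab$fused <- predict(fit, tab)
  }
  tab
}
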