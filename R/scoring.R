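#' Indices of the reverse-keyed questionnaire items
#'
#' Items 1-3 of the 12-item trust questionnaire are distrust-phrased
#' ("negative consequences", "must be cautious", "risky") and are scored as
#' `11 - value`; items 4-12 are trust-phrased and scored as-is. The keying
#' is isolated here so it can be audited or overridden in one place.
#'
#' @return Integer vector of reverse-keyed item indices.
#' @export
reverse_keyed_items <- function() 1:3

item_cols <- function() sprintf("item%02d", 1:12)

# Validate and extract a 12-item matrix from a response tibble.
item_matrix <- function(responses) {
  cols <- item_cols()
  missing <- setdiff(cols, names(responses))
  if (length(missing)) {
    stop_invalid(
      paste0("Missing item columns: ", paste(missing, collapse = ", ")),
      "trustfuse_validation_error"
    )
  }
  m <- as.matrix(responses[cols])
  bad <- which(!is.finite(m) | m < 1 | m > 10, arr.ind = TRUE)
  if (nrow(bad)) {
    stop_invalid(
      sprintf(
        "Item values out of range [1, 10] at item(s) %s.",
        paste(unique(bad[, "col"]), collapse = ", ")
      ),
      "trustfuse_validation_error"
    )
  }
  m
}

# Apply reverse keying: an involution (applying it twice is the identity).
apply_keying <- function(m) {
  m[, reverse_keyed_items()] <- 11 - m[, reverse_keyed_items()]
  m
}

#' Score questionnaire responses onto the 1-10 trust scale
#'
#' Reverse-scores the distrust-phrased items ([reverse_keyed_items()]) and
#' averages all 12 keyed items, keeping the score on the same 1-10 scale as
#' the EEG trust score so the two can be fused directly.
#'
#' @param responses Tibble with columns `item01`..`item12` (integers 1-10)
#'   and optionally `participant` / `event_id`.
#'
#' @return The input tibble with the item columns replaced by a `score`
#'   column in \[1, 10\].
#' @export
#' @examples
#' r <- simulate_questionnaire(0.8, seed = 1)
#' score_questionnaire(r)
score_questionnaire <- function(responses) {
  m <- apply_keying(item_matrix(responses))
  keep <- setdiff(names(responses), item_cols())
  out <- tibble::as_tibble(responses[keep])
  out$score <- rowMeans(m)
  out
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' `alpha = k / (k - 1) * (1 - sum(item variances) / variance(total score))`
#' with unbiased (n-1) sample variances, computed on keyed items.
#'
#' @param items Numeric matrix or data frame, respondents in rows, keyed
#'   items in columns.
#'
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop_invalid("Need >= 2 respondents and >= 2 items.", "trustfuse_invalid_argument")
  }
  k <- ncol(m)
  total_var <- var(rowSums(m))
  if (total_var == 0) {
    stop_invalid("Total-score variance is zero; alpha undefined.", "trustfuse_degenerate_input")
  }
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
}

#' Align per-event scores to an event timeline as a trust curve
#'
#' Joins scored responses to the timeline by `event_id`, attaches each
#' score at its event time and returns a time-sorted trust curve. Responses
#' referencing unknown events, or duplicated events for one participant,
#' raise an alignment error naming the offenders.
#'
#' @param scores Tibble with `participant`, `event_id` and `score`.
#' @param events Tibble with `event_id`, `t_start_s` and optionally
#'   `scenario`.
#' @param modality Modality label for the curve.
#'
#' @return A `trust_curve` tibble sorted by `t_s`.
#' @export
align_to_events <- function(scores, events, modality = "questionnaire") {
  orphans <- setdiff(scores$event_id, events$event_id)
  if (length(orphans)) {
    stop_invalid(
      paste0("Responses reference unknown events: ", paste(orphans, collapse = ", ")),
      "trustfuse_alignment_error"
    )
  }
  dup <- scores |>
    dplyr::count(.data$participant, .data$event_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop_invalid(
      paste0(
        "Duplicate responses for event(s): ",
        paste(unique(dup$event_id), collapse = ", ")
      ),
      "trustfuse_alignment_error"
    )
  }
  ev <- events[c("event_id", "t_start_s", intersect("scenario", names(events)))]
  if (!"scenario" %in% names(ev)) ev$scenario <- NA_character_
  out <- scores[setdiff(names(scores), c("scenario", "t_start_s"))] |>
    dplyr::inner_join(ev, by = "event_id") |>
    dplyr::transmute(
      participant = .data$participant,
      scenario = .data$scenario,
      event_id = .data$event_id,
      t_s = .data$t_start_s,
      modality = modality,
      score = .data$score
    ) |>
    dplyr::arrange(.data$t_s)
  new_trust_curve(out)
}

#' Scaling constants for behavioral trust scoring
#'
#' @param tau Latency scale in seconds: a decision latency of `tau` maps to
#'   a sub-score of `exp(-1)`.
#' @param c Count scale: `c` events of reliance / intervention /
#'   verification map to a sub-score of 0.5.
#' @return A list with elements `tau` and `c`.
#' @export
behavior_norms <- function(tau = 5, c = 3) list(tau = tau, c = c)

#' Score behavioral coding records onto the 0-10 trust scale
#'
#' Five normalized sub-scores in \[0, 1\] are averaged and scaled by 10:
#' `adherence_pct / 100`, `exp(-latency_s / tau)`, and `1 / (1 + count / c)`
#' for reliance, intervention and verification counts. Each sub-score is
#' monotone in the direction "more trusting behavior scores higher".
#'
#' @param coding Tibble with columns `adherence_pct`, `latency_s`,
#'   `reliance`, `interventions`, `verifications` (plus identifiers).
#' @param norms Scaling constants from [behavior_norms()].
#'
#' @return The input tibble with the indicator columns replaced by `score`
#'   in \[0, 10\].
#' @export
score_behavior <- function(coding, norms = behavior_norms()) {
  need <- c("adherence_pct", "latency_s", "reliance", "interventions", "verifications")
  missing <- setdiff(need, names(coding))
  if (length(missing)) {
    stop_invalid(
      paste0("Missing indicator columns: ", paste(missing, collapse = ", ")),
      "trustfuse_validation_error"
    )
  }
  counts <- as.matrix(coding[c("reliance", "interventions", "verifications")])
  if (any(counts < 0, na.rm = TRUE) || any(coding$latency_s < 0, na.rm = TRUE)) {
    stop_invalid("Counts and latency must be >= 0.", "trustfuse_validation_error")
  }
  if (any(coding$adherence_pct < 0 | coding$adherence_pct > 100)) {
    stop_invalid("`adherence_pct` must lie in [0, 100].", "trustfuse_validation_error")
  }
  sub <- cbind(
    coding$adherence_pct / 100,
    exp(-coding$latency_s / norms$tau),
    1 / (1 + coding$reliance / norms$c),
    1 / (1 + coding$interventions / norms$c),
    1 / (1 + coding$verifications / norms$c)
  )
  keep <- setdiff(names(coding), need)
  out <- tibble::as_tibble(coding[keep])
  out$score <- clip(10 * rowMeans(sub), 0, 10)
  out
}

#' Cohen's kappa for two raters
#'
#' Unweighted chance-corrected agreement `(p_o - p_e) / (1 - p_e)` between
#' two equal-length label sequences, with the large-sample standard error
#' and two-sided p-value for the null of chance agreement.
#'
#' @param rater_a,rater_b Label vectors (coerced to a common factor).
#'
#' @return A list: `kappa`, `p_observed`, `p_expected`, `se0`, `z`,
#'   `p_value`, `table` (the confusion matrix).
#' @export
#' @examples
#' interrater_kappa(c("L", "M", "H", "H"), c("L", "M", "M", "H"))
interrater_kappa <- function(rater_a, rater_b) {
  if (length(rater_a) != length(rater_b) || length(rater_a) < 2L) {
    stop_invalid("Need two equal-length label vectors with >= 2 observations.", "trustfuse_invalid_argument")
  }
  lev <- sort(unique(c(as.character(rater_a), as.character(rater_b))))
  a <- factor(as.character(rater_a), levels = lev)
  b <- factor(as.character(rater_b), levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pr <- rowSums(tab) / n
  pc <- colSums(tab) / n
  pe <- sum(pr * pc)
  if (pe >= 1) {
    stop_invalid("Expected agreement is 1; kappa undefined.", "trustfuse_degenerate_input")
  }
  kappa <- (po - pe) / (1 - pe)
  # Fleiss-Cohen-Everitt large-sample SE under H0: kappa = 0
  se0 <- sqrt((pe + pe^2 - sum(pr * pc * (pr + pc))) / (n * (1 - pe)^2))
  z <- if (se0 > 0) kappa / se0 else NA_real_
  list(
    kappa = kappa, p_observed = po, p_expected = pe,
    se0 = se0, z = z,
    p_value = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)),
    table = tab
  )
}
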