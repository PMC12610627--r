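#' Construct a single-channel EEG recording
#'
#' Bundles a sampled voltage trace with its sampling rate and the end of the
#' resting-state baseline segment recorded before the task. The recording is
#' an ordinary tibble (`time_s`, `eeg_uV`) carrying metadata attributes, so
#' it pipes through dplyr verbs untouched.
#'
#' @param data Data frame with numeric columns `time_s` (seconds, strictly
#'   increasing from 0) and `eeg_uV` (microvolts, no missing samples).
#' @param fs Sampling rate in Hz.
#' @param rest_end_s End of the resting baseline in seconds (default 10).
#' @param participant_id,scenario_id Optional identifiers.
#'
#' @return A `trustfuse_eeg` tibble.
#' @export
eeg_recording <- function(data, fs, rest_end_s = 10,
                          participant_id = NA_character_,
                          scenario_id = NA_character_) {
  stopifnot(is.data.frame(data), all(c("time_s", "eeg_uV") %in% names(data)))
  if (!is.numeric(fs) || fs <= 0) {
    stop_invalid("`fs` must be a positive sampling rate in Hz.", "trustfuse_invalid_argument")
  }
  if (anyNA(data$eeg_uV)) {
    stop_invalid("Recording contains missing samples; gaps are an input error.", "trustfuse_invalid_argument")
  }
  dur <- nrow(data) / fs
  if (dur <= rest_end_s) {
    stop_invalid("Recording must extend beyond the resting baseline.", "trustfuse_invalid_argument")
  }
  out <- tibble::as_tibble(data[c("time_s", "eeg_uV")])
  structure(out,
    class = c("trustfuse_eeg", class(out)),
    fs = fs, rest_end_s = rest_end_s,
    participant_id = participant_id, scenario_id = scenario_id
  )
}

eeg_meta <- function(recording) {
  list(
    fs = attr(recording, "fs"),
    rest_end_s = attr(recording, "rest_end_s"),
    participant_id = attr(recording, "participant_id"),
    scenario_id = attr(recording, "scenario_id")
  )
}

#' Preprocess an EEG recording
#'
#' Artifact-suppression chain applied before any spectral analysis:
#' zero-phase (forward-backward) FIR band-pass at 1-45 Hz, Daubechies-4
#' wavelet denoising (5 decomposition levels, soft universal threshold), and
#' a 5-sample median filter. Output has the same length and sampling rate.
#'
#' @param recording A `trustfuse_eeg` recording (see [eeg_recording()]).
#' @param bandpass Length-2 numeric, broadband pass limits in Hz.
#' @param wavelet_levels Wavelet decomposition depth.
#' @param median_k Median filter kernel length (samples).
#'
#' @return The preprocessed recording, same class and metadata.
#' @export
preprocess_eeg <- function(recording, bandpass = c(1, 45),
                           wavelet_levels = 5L, median_k = 5L) {
  meta <- eeg_meta(recording)
  if (meta$fs < 2 * bandpass[2]) {
    stop_invalid(
      sprintf("Sampling rate %g Hz cannot represent the %g Hz band edge.", meta$fs, bandpass[2]),
      "trustfuse_invalid_sampling_rate"
    )
  }
  if (nrow(recording) < 2 * meta$fs) {
    stop_invalid("Recording shorter than 2 s.", "trustfuse_invalid_argument")
  }
  x <- recording$eeg_uV
  x <- fir_filtfilt(x, fir_bandpass(meta$fs, bandpass[1], bandpass[2]))
  x <- wavelet_denoise(x, levels = wavelet_levels)
  x <- median_filter(x, k = median_k)
  out <- recording
  out$eeg_uV <- x
  out
}

#' Decompose an EEG recording into the five classical frequency bands
#'
#' Zero-phase FIR band-pass filtering at the delta (1-4), theta (4-8),
#' alpha (8-13), beta (13-30) and gamma (30-45 Hz) limits. The decomposition
#' is a quality-control view; trust scoring integrates the broadband Welch
#' spectrum over the band limits instead (see [compute_trust_curve()]).
#'
#' @inheritParams preprocess_eeg
#' @return A long tibble with columns `time_s`, `band` (ordered factor) and
#'   `eeg_uV`, one band-limited series per band, each the length of the input.
#' @export
band_decompose <- function(recording) {
  meta <- eeg_meta(recording)
  bands <- eeg_bands()
  purrr::imap_dfr(bands, function(lim, nm) {
    tibble::tibble(
      time_s = recording$time_s,
      band = nm,
      eeg_uV = fir_filtfilt(recording$eeg_uV, fir_bandpass(meta$fs, lim[1], lim[2]))
    )
  }) |>
    dplyr::mutate(band = factor(.data$band, levels = names(bands)))
}

#' Map a standardized alpha/beta ratio to the trust scale
#'
#' The bounded mapping `5 + 2.5 * tanh(z)` centres the score at the scale
#' midpoint (a standardized ratio of 0 scores exactly 5) and confines all
#' scores to the open interval (2.5, 7.5), avoiding floor and ceiling
#' effects: z near +/-2 maps to roughly 3-8 on the 1-10 scale.
#'
#' @param z Numeric vector of standardized alpha/beta ratios.
#' @return Trust scores on the 1-10 scale, in (2.5, 7.5).
#' @export
#' @examples
#' zscore_to_trust(c(-Inf, -1, 0, 1, Inf))
zscore_to_trust <- function(z) 5 + 2.5 * tanh(z)

#' Per-event band powers and alpha/beta ratios
#'
#' Cuts 3 s epochs (-1 to +2 s around each decision point), computes Welch
#' power in all five classical bands and the alpha/beta ratio. Epochs
#' extending past the recording are skipped with a warning; epochs whose beta
#' power is below `beta_floor` are flagged invalid rather than yielding an
#' unbounded ratio.
#'
#' @inheritParams preprocess_eeg
#' @param events Data frame with columns `event_id` and `t_start_s` (decision
#'   points, seconds from recording start).
#' @param epoch_window Length-2 numeric, epoch limits in seconds relative to
#'   the decision point.
#' @param welch_window_s Welch segment length in seconds.
#' @param beta_floor Minimum admissible beta power (µV²).
#'
#' @return Tibble with one row per event: `event_id`, `t_s`, the five band
#'   powers, `ratio` and `valid`.
#' @export
epoch_band_powers <- function(recording, events, epoch_window = c(-1, 2),
                              welch_window_s = 2, beta_floor = 1e-12) {
  meta <- eeg_meta(recording)
  stopifnot(all(c("event_id", "t_start_s") %in% names(events)))
  n <- nrow(recording)
  bands <- eeg_bands()
  rows <- purrr::pmap_dfr(
    list(events$event_id, events$t_start_s),
    function(eid, t0) {
      i0 <- as.integer(round((t0 + epoch_window[1]) * meta$fs)) + 1L
      i1 <- i0 + as.integer(round(diff(epoch_window) * meta$fs)) - 1L
      if (i0 < 1L || i1 > n || (t0 + epoch_window[1]) < meta$rest_end_s) {
        warning(sprintf("Event %s: epoch outside the task segment; skipped.", eid))
        return(NULL)
      }
      seg <- recording$eeg_uV[i0:i1]
      psd <- welch_psd(seg, meta$fs, window_s = welch_window_s)
      pw <- vapply(bands, function(b) band_power_from_psd(psd, b), numeric(1))
      tibble::tibble(
        event_id = eid, t_s = t0,
        delta = pw[["delta"]], theta = pw[["theta"]], alpha = pw[["alpha"]],
        beta = pw[["beta"]], gamma = pw[["gamma"]],
        ratio = if (pw[["beta"]] > beta_floor) pw[["alpha"]] / pw[["beta"]] else NA_real_,
        valid = pw[["beta"]] > beta_floor
      )
    }
  )
  rows
}

#' EEG trust curve from a recording and its event timeline
#'
#' Full scoring pipeline: preprocessing ([preprocess_eeg()]), resting
#' baseline alpha/beta ratio from the first `rest_end_s` seconds, per-event
#' 3 s epoch band powers, z-standardization of the epoch ratios across all
#' task epochs of the recording (`Z = (X - mu) / sigma`), and the bounded
#' mapping `5 + 2.5 * tanh(Z)` onto the trust scale
#' ([zscore_to_trust()]).
#'
#' The baseline ratio is stored alongside the curve as an individual
#' reference state but does not enter the score arithmetic; standardization
#' uses the mean and standard deviation of the task-epoch ratios themselves.
#'
#' @inheritParams epoch_band_powers
#' @param preprocess If `FALSE`, the recording is assumed already
#'   preprocessed.
#'
#' @return A `trust_curve` tibble with columns `participant`, `scenario`,
#'   `event_id`, `t_s`, `modality` (`"eeg"`), `ratio`, `z` and `score`;
#'   attributes `standardization` (mu, sigma of the epoch ratios),
#'   `baseline_ratio` and `skipped` (event ids).
#' @export
compute_trust_curve <- function(recording, events, epoch_window = c(-1, 2),
                                welch_window_s = 2, preprocess = TRUE) {
  if (nrow(events) < 2L) {
    stop_invalid("At least 2 events are required to standardize epoch ratios.", "trustfuse_invalid_argument")
  }
  meta <- eeg_meta(recording)
  rec <- if (preprocess) preprocess_eeg(recording) else recording
  n_rest <- as.integer(round(meta$rest_end_s * meta$fs))
  rest <- rec$eeg_uV[seq_len(n_rest)]
  rest_psd <- welch_psd(rest, meta$fs, window_s = welch_window_s)
  baseline_ratio <- band_power_from_psd(rest_psd, eeg_bands()$alpha) /
    band_power_from_psd(rest_psd, eeg_bands()$beta)
  bp <- epoch_band_powers(rec, events,
    epoch_window = epoch_window,
    welch_window_s = welch_window_s
  )
  skipped <- setdiff(events$event_id, bp$event_id)
  bp <- dplyr::filter(bp, .data$valid)
  if (nrow(bp) < 2L) {
    stop_invalid("Fewer than 2 valid epochs; cannot standardize.", "trustfuse_degenerate_input")
  }
  mu <- mean(bp$ratio)
  sigma <- sd(bp$ratio)
  if (sigma == 0) {
    stop_invalid("Epoch ratios have zero dispersion; z-scores undefined.", "trustfuse_degenerate_input")
  }
  z <- (bp$ratio - mu) / sigma
  out <- tibble::tibble(
    participant = meta$participant_id,
    scenario = meta$scenario_id,
    event_id = bp$event_id,
    t_s = bp$t_s,
    modality = "eeg",
    ratio = bp$ratio,
    z = z,
    score = zscore_to_trust(z)
  )
  new_trust_curve(out,
    standardization = list(mu = mu, sigma = sigma),
    baseline_ratio = baseline_ratio,
    skipped = skipped
  )
}

new_trust_curve <- function(data, ...) {
  extra <- list(...)
  out <- tibble::as_tibble(data)
  class(out) <- c("trust_curve", class(out))
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

#' @export
print.trust_curve <- function(x, ...) {
  mod <- unique(x$modality)
  cat(sprintf(
    "<trust_curve> %d events, modality: %s\n",
    nrow(x), paste(mod, collapse = ", ")
  ))
  NextMethod()
}
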