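#' Welch power spectral density estimate
#'
#' Averages modified periodograms of Hann-windowed, 50%-overlapping segments.
#' The window length defaults to 2 s of signal (1000 samples at 500 Hz); when
#' the segment is shorter than one window the whole segment is used as a
#' single window, in which case the estimate equals the plain Hann-tapered
#' periodogram computed from the discrete Fourier transform.
#'
#' @param x Numeric vector, the signal (microvolts).
#' @param fs Sampling rate in Hz.
#' @param window_s Segment length in seconds (default 2).
#' @param overlap Fractional overlap between segments (default 0.5).
#'
#' @return A tibble with columns `freq` (Hz) and `psd` (power spectral
#'   density, µV²/Hz, one-sided).
#' @export
#' @examples
#' t <- seq(0, 4, by = 1 / 500)
#' psd <- welch_psd(sin(2 * pi * 10 * t), fs = 500)
#' psd$freq[which.max(psd$psd)] # close to 10 Hz
welch_psd <- function(x, fs, window_s = 2, overlap = 0.5) {
  if (length(x) == 0L) {
    stop_invalid("`x` must be a non-empty numeric vector.", "trustfuse_invalid_argument")
  }
  n <- min(as.integer(round(window_s * fs)), length(x))
  step <- max(1L, as.integer(round(n * (1 - overlap))))
  starts <- seq.int(1L, length(x) - n + 1L, by = step)
  # periodic Hann window
  k <- seq_len(n) - 1L
  w <- 0.5 * (1 - cos(2 * pi * k / n))
  scale <- fs * sum(w^2)
  nfreq <- n %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + n - 1L)] * w
    sp <- fft(seg)[seq_len(nfreq)]
    acc <- acc + (Mod(sp)^2) / scale
  }
  pxx <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when n is even)
  dbl <- rep(2, nfreq)
  dbl[1L] <- 1
  if (n %% 2L == 0L) dbl[nfreq] <- 1
  tibble::tibble(freq = (seq_len(nfreq) - 1L) * fs / n, psd = pxx * dbl)
}

#' Band power from a Welch spectrum
#'
#' Integrates the one-sided Welch PSD over a frequency band by the
#' trapezoidal rule across the PSD bins falling inside the band.
#'
#' @inheritParams welch_psd
#' @param band Length-2 numeric, band edges in Hz (e.g. `c(8, 13)` for alpha).
#'
#' @return Scalar band power in µV².
#' @export
#' @examples
#' t <- seq(0, 4 - 1 / 500, by = 1 / 500)
#' welch_band_power(sin(2 * pi * 10 * t), fs = 500, band = c(8, 13)) # ~0.5
welch_band_power <- function(x, fs, band, window_s = 2, overlap = 0.5) {
  band_power_from_psd(welch_psd(x, fs, window_s = window_s, overlap = overlap), band)
}

# Trapezoidal integral of an already-computed PSD over one band.
band_power_from_psd <- function(psd, band) {
  stopifnot(length(band) == 2L, band[1] < band[2])
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  if (sum(sel) < 2L) {
    stop_invalid(
      "Frequency resolution too coarse for the requested band.",
      "trustfuse_invalid_argument"
    )
  }
  f <- psd$freq[sel]
  p <- psd$psd[sel]
  sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2)
}

# Canonical EEG band limits (Hz).
eeg_bands <- function() {
  list(
    delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
    beta = c(13, 30), gamma = c(30, 45)
  )
}
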