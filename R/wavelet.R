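# Periodized orthogonal wavelet transform with the Daubechies 4-vanishing-
# moment filter pair (8 taps, PyWavelets' "db4"), plus the soft-threshold
# denoiser used in EEG preprocessing. Written in vectorized R: each filter
# tap is one strided gather/scatter, so cost is O(8 n) per level.

# db4 orthonormal scaling (low-pass) coefficients; sum = sqrt(2).
db4_lowpass <- c(
  0.230377813308855230, 0.714846570552541500, 0.630880767929590400,
  -0.027983769416983850, -0.187034811718881140, 0.030841381835986965,
  0.032883011666982945, -0.010597401784997278
)

db4_highpass <- function() {
  h <- db4_lowpass
  l <- length(h)
  rev(h) * (-1)^(seq_len(l) - 1L)
}

# One analysis level, periodic boundary. x must have even length.
dwt_step <- function(x) {
  n <- length(x)
  stopifnot(n %% 2L == 0L)
  h <- db4_lowpass
  g <- db4_highpass()
  k2 <- 2L * (seq_len(n %/% 2L) - 1L)
  a <- numeric(n %/% 2L)
  d <- numeric(n %/% 2L)
  for (m in seq_along(h)) {
    idx <- (k2 + (m - 1L)) %% n + 1L
    a <- a + h[m] * x[idx]
    d <- d + g[m] * x[idx]
  }
  list(a = a, d = d)
}

# One synthesis level, adjoint of dwt_step (orthonormal, so exact inverse).
idwt_step <- function(a, d) {
  nk <- length(a)
  n <- 2L * nk
  h <- db4_lowpass
  g <- db4_highpass()
  x <- numeric(n)
  k2 <- 2L * (seq_len(nk) - 1L)
  for (m in seq_along(h)) {
    idx <- (k2 + (m - 1L)) %% n + 1L
    x[idx] <- x[idx] + h[m] * a + g[m] * d
  }
  x
}

# Multilevel periodized DWT; pads with zeros to a multiple of 2^levels and
# records the original length for reconstruction.
dwt_db4 <- function(x, levels = 5L) {
  n0 <- length(x)
  block <- 2L^levels
  npad <- (block - n0 %% block) %% block
  xa <- c(x, numeric(npad))
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    st <- dwt_step(xa)
    details[[j]] <- st$d
    xa <- st$a
  }
  list(approx = xa, details = details, n = n0, levels = levels)
}

idwt_db4 <- function(decomp) {
  a <- decomp$approx
  for (j in rev(seq_len(decomp$levels))) {
    a <- idwt_step(a, decomp$details[[j]])
  }
  a[seq_len(decomp$n)]
}

soft_threshold <- function(x, lambda) sign(x) * pmax(abs(x) - lambda, 0)

# Donoho-style denoiser: universal threshold lambda = sigma * sqrt(2 log n),
# sigma from the median absolute deviation of the finest detail level
# (MAD / 0.6745); soft shrinkage applied to all detail levels, the
# approximation is left untouched.
wavelet_denoise <- function(x, levels = 5L) {
  dec <- dwt_db4(x, levels = levels)
  sigma <- stats::median(abs(dec$details[[1L]])) / 0.6745
  lambda <- sigma * sqrt(2 * log(length(x)))
  dec$details <- lapply(dec$details, soft_threshold, lambda = lambda)
  idwt_db4(dec)
}
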