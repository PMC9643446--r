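# Internal numerical utilities: FFT-based zero-phase filtering, analytic
# signals, coloured-noise and fractional-Gaussian-noise generators.

.resteeg_cache <- new.env(parent = emptyenv())

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analytic signal via the frequency-domain Hilbert construction
#' @param x numeric vector
#' @return complex vector, Re = x, Mod = amplitude envelope
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Real, non-negative zero-phase frequency response of a band-pass filter with
# raised-cosine transitions. Transition width defaults to 25% of each band
# edge. Returned on the two-sided FFT grid of length n at sampling rate fs.
band_response <- function(n, fs, f_lo, f_hi, trans_frac = 0.25) {
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)           # fold to [0, fs/2]
  H <- numeric(n)
  tw_lo <- max(trans_frac * f_lo, 1e-6)
  tw_hi <- max(trans_frac * f_hi, 1e-6)
  lo0 <- max(f_lo - tw_lo, 0)
  hi1 <- f_hi + tw_hi
  pass <- f >= f_lo & f <= f_hi
  H[pass] <- 1
  ramp_up <- f > lo0 & f < f_lo
  H[ramp_up] <- 0.5 * (1 - cos(pi * (f[ramp_up] - lo0) / (f_lo - lo0)))
  ramp_dn <- f > f_hi & f < hi1
  H[ramp_dn] <- 0.5 * (1 + cos(pi * (f[ramp_dn] - f_hi) / (hi1 - f_hi)))
  H
}

# Zero-phase notch response (raised-cosine shoulders around the stop band).
notch_response <- function(n, fs, f0, half_width = 1, trans = 0.5) {
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  H <- rep(1, n)
  d <- abs(f - f0)
  H[d <= half_width] <- 0
  sh <- d > half_width & d < half_width + trans
  H[sh] <- 0.5 * (1 - cos(pi * (d[sh] - half_width) / trans))
  H
}

#' Zero-phase filter a matrix of signals (columns) by a real response
#' @param x numeric matrix (samples x channels) or vector
#' @param H real response on the length-n FFT grid
#' @noRd
apply_response <- function(x, H) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  y <- Re(stats::mvfft(stats::mvfft(x) * H, inverse = TRUE)) / nrow(x)
  if (vec) drop(y) else y
}

# Analytic band signal in one pass: positive-frequency half of the zero-phase
# band response, doubled. Returns complex matrix, same shape as x.
analytic_band <- function(x, fs, f_lo, f_hi, trans_frac = 0.25) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  H <- band_response(n, fs, f_lo, f_hi, trans_frac)
  fidx <- (0:(n - 1))
  Ha <- H
  Ha[fidx > n / 2] <- 0                     # kill negative frequencies
  Ha[fidx > 0 & fidx < n / 2] <- 2 * Ha[fidx > 0 & fidx < n / 2]
  z <- stats::mvfft(stats::mvfft(x) * Ha, inverse = TRUE) / n
  if (vec) drop(z) else z
}

#' Gaussian noise with an exact power-law spectrum, PSD ~ f^(-chi)
#'
#' Spectral shaping of white Gaussian noise by |H(f)| = f^(-chi/2); DC is
#' zeroed. Output is standardized to the requested standard deviation.
#' @noRd
powerlaw_noise <- function(n, fs, chi, sd = 1) {
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  H <- ifelse(f > 0, f^(-chi / 2), 0)
  z <- stats::fft(stats::rnorm(n))
  x <- Re(stats::fft(z * H, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s * sd
}

#' Fractional Gaussian noise by circulant embedding (Davies-Harte)
#'
#' Exact-covariance sampling of fGn with Hurst parameter `H` in (0,1).
#' @noRd
fgn_davies_harte <- function(n, hurst) {
  stopifnot(hurst > 0, hurst < 1)
  k <- 0:n
  g <- 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
              abs(k - 1)^(2 * hurst))
  m <- 2 * n
  c_row <- c(g, g[n:2])
  lam <- Re(stats::fft(c_row))
  lam[lam < 0] <- 0               # guard tiny negative round-off
  z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  x <- stats::fft(sqrt(lam / (2 * m)) * z)
  Re(x)[1:n]
}

# Truncated-normal draws on [lo, hi] by rejection sampling.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# Constant-amplitude oscillator with Ornstein-Uhlenbeck frequency jitter.
# Centre frequency f0 Hz, approximate spectral full width `bw` Hz, jitter
# correlation time `tau` s. The Hilbert envelope is ~1 by construction.
phase_jitter_osc <- function(n, fs, f0, bw, tau = 0.2) {
  if (bw <= 0) {
    ph0 <- stats::runif(1, 0, 2 * pi)
    return(cos(2 * pi * f0 * (0:(n - 1)) / fs + ph0))
  }
  a <- exp(-1 / (tau * fs))
  e <- stats::rnorm(n, 0, (bw / 2) * sqrt(1 - a^2))
  df <- as.numeric(stats::filter(e, a, method = "recursive"))
  ph0 <- stats::runif(1, 0, 2 * pi)
  cos(2 * pi * cumsum(f0 + df) / fs + ph0)
}

# Deterministic 32-bit FNV-1a hash of a character scalar (manifest hashing).
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) + (h %/% 2^31) * 2^31
    # 32-bit modular multiply by the FNV prime, split to stay exact in doubles
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
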