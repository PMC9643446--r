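# Criticality biomarkers: long-range temporal correlations of amplitude
# envelopes (detrended fluctuation analysis) and the functional
# excitation/inhibition ratio (fEI).

#' Amplitude envelope of a band-filtered signal
#'
#' Epochs are concatenated in temporal order, band-pass filtered with a
#' zero-phase filter, and the envelope taken as the magnitude of the
#' analytic signal. Half a second at each end is flagged for trimming
#' (filter edge artifacts); [dfa()] and [fei()] honour the flag.
#'
#' @param er an [epoched_recording()]
#' @param band `c(lo, hi)` in Hz or a band name from [band_set()]
#' @param patch patch index or label
#' @param trim_s seconds flagged for trimming at each end (default 0.5)
#' @return object of class `envelope_signal`: list with `envelope`
#'   (non-negative numeric vector, full length), `fs`, `band`, `trim`
#'   (samples to drop at each end)
#' @export
band_envelope <- function(er, band, patch = 1, trim_s = 0.5) {
  if (is.character(band) && length(band) == 1) band <- band_set()[[band]]
  if (band[2] > er$fs / 2) stop("band above Nyquist")
  if (is.character(patch)) patch <- match(patch, er$patch_labels)
  x <- concat_epochs(er)[, patch]
  z <- analytic_band(x, er$fs, band[1], band[2])
  structure(list(envelope = Mod(z), fs = er$fs, band = band,
                 trim = round(trim_s * er$fs)),
            class = "envelope_signal")
}

# strip the edge-trim region of an envelope
env_values <- function(env) {
  e <- env$envelope
  tr <- env$trim %||% 0
  if (tr > 0 && length(e) > 2 * tr) e <- e[(tr + 1):(length(e) - tr)]
  e
}

#' Detrended fluctuation analysis
#'
#' Demeans the signal, integrates it to a profile, and for logarithmically
#' spaced window sizes splits the profile into 50%-overlapping windows,
#' removes each window's linear trend and averages the per-window RMS. The
#' DFA exponent is the least-squares slope of `log10 F(s)` versus
#' `log10 s`. An exponent of 0.5 indicates uncorrelated increments; larger
#' values indicate persistent long-range temporal correlations.
#'
#' @param env an [band_envelope()] result, or a plain numeric vector (then
#'   `fs` must be given)
#' @param fit_lo_s,fit_hi_s fitted window-size range in seconds
#'   (default 2-20)
#' @param n_scales number of log-spaced window sizes (default 15)
#' @param fs sampling rate, required when `env` is a plain vector
#' @return object of class `dfa_result`: `exponent`, `scales_s`,
#'   `fluctuation`, `r_squared`
#' @export
dfa <- function(env, fit_lo_s = 2, fit_hi_s = 20, n_scales = 15, fs = NULL) {
  if (inherits(env, "envelope_signal")) {
    x <- env_values(env)
    fs <- env$fs
  } else {
    if (is.null(fs)) stop("fs required for plain vectors")
    x <- as.numeric(env)
  }
  n <- length(x)
  if (n < 2 * fit_hi_s * fs) stop("signal shorter than twice the largest window")
  if (stats::sd(x) == 0) stop("constant signal: fluctuation undefined")
  prof <- cumsum(x - mean(x))
  scales <- unique(round(exp(seq(log(fit_lo_s * fs), log(fit_hi_s * fs),
                                 length.out = n_scales))))
  pre <- dfa_prefix(prof)
  Fl <- vapply(scales, function(s) .dfa_fluct(prof, s, pre), 0)
  if (any(Fl <= 0)) stop("degenerate fluctuation (perfectly linear profile)")
  lx <- log10(scales / fs)
  ly <- log10(Fl)
  co <- stats::lm.fit(cbind(1, lx), ly)$coefficients
  r2 <- 1 - sum((ly - (co[1] + co[2] * lx))^2) / sum((ly - mean(ly))^2)
  structure(list(exponent = unname(co[2]), scales_s = scales / fs,
                 fluctuation = Fl, r_squared = r2),
            class = "dfa_result")
}

# mean per-window RMS of linear-detrend residuals, windows 50% overlapping.
# Regression sums per window come from global prefix sums in O(1) each
# (R's cumsum uses an extended-precision accumulator, which keeps the
# subtractive cancellation benign at these magnitudes).
.dfa_fluct <- function(prof, s, pre = NULL) {
  n <- length(prof)
  starts <- seq(1, n - s + 1, by = max(1, s %/% 2))
  if (is.null(pre)) pre <- dfa_prefix(prof)
  a <- starts; b <- starts + s - 1
  Sy  <- pre$c1[b + 1] - pre$c1[a]
  Sgy <- pre$c3[b + 1] - pre$c3[a]
  Syy <- pre$c2[b + 1] - pre$c2[a]
  # local time index i = g - a + 1
  Sty <- Sgy - (a - 1) * Sy
  t_sum <- s * (s + 1) / 2
  tt_sum <- s * (s + 1) * (2 * s + 1) / 6
  Stc <- tt_sum - t_sum^2 / s
  Sty_c <- Sty - t_sum * Sy / s
  Syy_c <- Syy - Sy^2 / s
  rss <- pmax(Syy_c - Sty_c^2 / Stc, 0)
  mean(sqrt(rss / s))
}

dfa_prefix <- function(prof) {
  g <- seq_along(prof)
  list(c1 = c(0, cumsum(prof)),
       c2 = c(0, cumsum(prof * prof)),
       c3 = c(0, cumsum(g * prof)))
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("<dfa_result> exponent %.3f over %g-%g s (R2 %.3f)\n",
              x$exponent, min(x$scales_s), max(x$scales_s), x$r_squared))
  invisible(x)
}

#' Functional excitation/inhibition ratio
#'
#' Partitions the amplitude envelope into non-overlapping windows. Per
#' window: the mean amplitude `wA`; then the window's envelope is divided
#' by `wA`, demeaned and integrated, a linear trend removed, and the
#' residual SD taken as the normalized fluctuation `wF`. fEI is one minus
#' the Pearson correlation between `wA` and `wF` across windows: about 1 at
#' criticality, below 1 when inhibition dominates, above 1 when excitation
#' dominates. The estimate is conventionally considered valid only where
#' the envelope shows long-range correlations (DFA exponent >= 0.6).
#'
#' @param env a [band_envelope()] result or numeric vector (with `fs`)
#' @param window_s window length in seconds (default 5)
#' @param dfa_exponent optional DFA exponent used for the validity flag
#' @param fs sampling rate for plain vectors
#' @return object of class `fei_result`: `fei`, `wA`, `wF`, `valid`
#' @export
fei <- function(env, window_s = 5, dfa_exponent = NA, fs = NULL) {
  if (inherits(env, "envelope_signal")) {
    x <- env_values(env)
    fs <- env$fs
  } else {
    if (is.null(fs)) stop("fs required for plain vectors")
    x <- as.numeric(env)
  }
  s <- round(window_s * fs)
  nw <- length(x) %/% s
  if (nw < 10) stop("need at least 10 windows for fEI")
  x <- x[seq_len(nw * s)]
  W <- matrix(x, nrow = s)
  wA <- colMeans(W)
  if (any(wA <= 0)) stop("non-positive window amplitude")
  Wn <- sweep(W, 2, wA, "/")
  prof <- apply(Wn - rep(colMeans(Wn), each = s), 2, cumsum)
  t <- seq_len(s)
  St <- sum(t); Stt <- sum(t * t); Stc <- Stt - St^2 / s
  Sy <- colSums(prof)
  Sty <- as.vector(crossprod(t, prof))
  Syy <- colSums(prof * prof)
  Sty_c <- Sty - St * Sy / s
  Syy_c <- Syy - Sy^2 / s
  rss <- pmax(Syy_c - Sty_c^2 / Stc, 0)
  wF <- sqrt(rss / (s - 1))
  if (stats::sd(wA) == 0 || stats::sd(wF) == 0) {
    stop("degenerate window statistics (zero variance)")
  }
  structure(list(fei = 1 - stats::cor(wA, wF), wA = wA, wF = wF,
                 valid = is.na(dfa_exponent) || dfa_exponent >= 0.6),
            class = "fei_result")
}

#' @export
print.fei_result <- function(x, ...) {
  cat(sprintf("<fei_result> fEI %.3f over %d windows%s\n", x$fei,
              length(x$wA), if (x$valid) "" else " (flagged invalid: weak LRTC)"))
  invisible(x)
}
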