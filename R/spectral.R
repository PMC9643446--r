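# Multitaper spectral estimation and spectral biomarkers: absolute/relative
# band power, hemispheric asymmetry, theta/beta ratio, peak alpha frequency
# and the aperiodic 1/f exponent.

#' Discrete prolate spheroidal (Slepian) sequences
#'
#' Computed from the standard symmetric tridiagonal eigenproblem and cached;
#' tapers are unit-energy with the conventional polarity (odd-order tapers
#' have positive mean).
#'
#' @param n sequence length in samples
#' @param nw time-half-bandwidth product
#' @param k number of tapers (default `2*nw - 1`)
#' @return n x k matrix of tapers
#' @export
dpss_tapers <- function(n, nw, k = max(1, floor(2 * nw - 1))) {
  key <- paste(n, nw, k, sep = "_")
  hit <- .resteeg_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  i <- 0:(n - 1)
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  V <- eigen(A, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- V[, j] / sqrt(sum(V[, j]^2))
    if (j %% 2 == 1 && sum(v) < 0) v <- -v
    if (j %% 2 == 0 && sum((seq_len(n) - (n + 1) / 2) * v) < 0) v <- -v
    V[, j] <- v
  }
  .resteeg_cache[[key]] <- V
  V
}

#' Multitaper power spectral density of an epoched recording
#'
#' Per-epoch DPSS-tapered spectra averaged over tapers and epochs, scaled as
#' a one-sided density so that the integral over `[0, fs/2]` equals the mean
#' signal variance (Parseval).
#'
#' @param er an [epoched_recording()]
#' @param half_bandwidth spectral half-bandwidth W in Hz (default 1);
#'   `W * epoch_len_s` must be at least 1
#' @return object of class `spectral_estimate`: list with `freqs` (Hz),
#'   `psd` (patches x freqs), `n_epochs`, `half_bandwidth`, `n_tapers`
#' @export
multitaper_psd <- function(er, half_bandwidth = 1) {
  ne <- n_epochs(er)
  if (ne == 0) stop("no epochs")
  nw <- half_bandwidth * er$epoch_len_s
  if (nw < 1) stop("half_bandwidth * epoch_len_s must be >= 1")
  spe <- dim(er$epochs)[3]
  P <- dim(er$epochs)[2]
  k <- max(1, floor(2 * nw - 1))
  V <- dpss_tapers(spe, nw, k)
  nf <- spe %/% 2 + 1
  acc <- matrix(0, nf, P)
  for (e in seq_len(ne)) {
    ep <- t(er$epochs[e, , , drop = TRUE])
    if (P == 1) ep <- matrix(er$epochs[e, 1, ], ncol = 1)
    for (j in seq_len(k)) {
      X <- stats::mvfft(ep * V[, j])
      acc <- acc + Mod(X[seq_len(nf), , drop = FALSE])^2
    }
  }
  psd <- acc / (ne * k * er$fs)
  psd[2:(nf - 1), ] <- 2 * psd[2:(nf - 1), ]     # one-sided
  structure(list(freqs = (0:(nf - 1)) * er$fs / spe,
                 psd = t(psd), n_epochs = ne,
                 half_bandwidth = half_bandwidth, n_tapers = k,
                 patch_labels = er$patch_labels),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> %d patches, %d freqs (%g-%g Hz), %d epochs x %d tapers\n",
              nrow(x$psd), length(x$freqs), min(x$freqs), max(x$freqs),
              x$n_epochs, x$n_tapers))
  invisible(x)
}

# indices of the PSD grid falling in [lo, hi) -- bands share edges, so a
# half-open convention makes the five bands a partition of the full range.
band_bins <- function(freqs, lo, hi, closed_hi = FALSE) {
  if (closed_hi) which(freqs >= lo & freqs <= hi) else which(freqs >= lo & freqs < hi)
}

#' Absolute and relative band power per patch
#'
#' Absolute power integrates the PSD over each band; relative power divides
#' by the integral over the full analysis range (1.25-48 Hz by default), so
#' the five relative powers per patch sum to one.
#'
#' @param se a [spectral_estimate()]
#' @param bands a [band_set()]
#' @return list with matrices `absolute` and `relative` (patches x bands)
#' @export
band_power <- function(se, bands = band_set()) {
  rng <- band_range(bands)
  df <- se$freqs[2] - se$freqs[1]
  if (rng[1] < min(se$freqs) - df / 2 || rng[2] > max(se$freqs) + df / 2) {
    stop("band range outside the spectral grid")
  }
  full <- band_bins(se$freqs, rng[1], rng[2], closed_hi = TRUE)
  total <- rowSums(se$psd[, full, drop = FALSE]) * df
  absolute <- sapply(names(bands), function(nm) {
    b <- bands[[nm]]
    hi_closed <- abs(b[2] - rng[2]) < 1e-9        # last band keeps its top edge
    idx <- band_bins(se$freqs, b[1], b[2], closed_hi = hi_closed)
    rowSums(se$psd[, idx, drop = FALSE]) * df
  })
  absolute <- matrix(absolute, nrow = nrow(se$psd),
                     dimnames = list(se$patch_labels, names(bands)))
  list(absolute = absolute, relative = absolute / total)
}

#' Hemispheric power asymmetry per region and band
#'
#' Right-minus-left absolute power per homotopic patch pair, averaged over
#' the pairs within each of the six regions.
#'
#' @param bp output of [band_power()]
#' @param scheme a [region_scheme()]
#' @return regions x bands matrix
#' @export
power_asymmetry <- function(bp, scheme) {
  pairs <- homotopic_pairs(scheme)
  abs_p <- bp$absolute
  diffs <- abs_p[pairs$rh, , drop = FALSE] - abs_p[pairs$lh, , drop = FALSE]
  regions <- unique(pairs$region)
  out <- t(sapply(regions, function(r) {
    colMeans(diffs[pairs$region == r, , drop = FALSE])
  }))
  rownames(out) <- regions
  out
}

#' Theta/beta power ratio per region (hemispheres pooled)
#'
#' @param bp output of [band_power()]
#' @param scheme a [region_scheme()]
#' @return named vector, one ratio per region
#' @export
theta_beta_ratio <- function(bp, scheme) {
  th <- bp$absolute[, "theta"]
  be <- bp$absolute[, "beta"]
  if (any(be <= 0)) stop("zero beta power: ratio undefined")
  ratio <- th / be
  regions <- unique(scheme$region)
  out <- vapply(regions, function(r) {
    mean(ratio[scheme$patch[scheme$region == r]])
  }, 0)
  names(out) <- regions
  out
}

#' Aperiodic (1/f) fit with iterative Gaussian peak removal
#'
#' Spectral parametrization in the style of specparam: (1) robust log-log
#' linear fit of the PSD over the fit range, (2) iterative Gaussian peak
#' fitting on the flattened spectrum (up to `max_peaks` peaks of height at
#' least `2 * residual SD` and at least `min_peak_height` log10-units, width
#' bounded to `[0.5, 12]` Hz), (3) aperiodic refit on the peak-subtracted
#' spectrum. The exponent is the negative log-log slope. Peak alpha
#' frequency (PAF) is the centre of the highest Gaussian with centre in
#' 8-13 Hz, falling back to the flattened-spectrum argmax in 8-13 Hz when no
#' peak qualifies.
#'
#' @param freqs frequency grid (Hz)
#' @param psd power spectral density values (> 0 over the fit range)
#' @param fit_range frequency range for the fit (default `c(1.25, 48)`)
#' @param max_peaks maximum number of Gaussian peaks (default 6)
#' @param min_peak_height absolute minimum peak height in log10-power units
#' @return object of class `aperiodic_fit`: list with `exponent`, `offset`,
#'   `peaks` (data.frame: center, height, width), `paf`, `paf_from_peak`,
#'   `fit_range`, `r_squared`
#' @export
fit_aperiodic <- function(freqs, psd, fit_range = c(1.25, 48), max_peaks = 6,
                          min_peak_height = 0.05) {
  sel <- freqs >= fit_range[1] & freqs <= fit_range[2]
  f <- freqs[sel]
  p <- psd[sel]
  if (any(p <= 0)) stop("non-positive PSD in fit range")
  lf <- log10(f)
  lp <- log10(p)

  line_fit <- function(y, w = NULL) {
    fit <- if (is.null(w)) stats::lm.fit(cbind(1, lf), y)
           else stats::lm.wfit(cbind(1, lf), y, w)
    fit$coefficients
  }
  # initial fit, then robust refit using only points at or below the line's
  # neighbourhood (peaks sit above the aperiodic component)
  co <- line_fit(lp)
  res <- lp - (co[1] + co[2] * lf)
  thresh <- stats::quantile(res, 0.5)
  co <- line_fit(lp, w = as.numeric(res <= thresh + 1e-12))
  flat <- lp - (co[1] + co[2] * lf)

  peaks <- data.frame(center = numeric(0), height = numeric(0),
                      width = numeric(0))
  work <- flat
  for (it in seq_len(max_peaks)) {
    sd_r <- stats::sd(work)
    i0 <- which.max(work)
    h <- work[i0]
    if (h < 2 * sd_r || h < min_peak_height) break
    # half-height width estimate
    half <- h / 2
    iL <- i0; while (iL > 1 && work[iL] > half) iL <- iL - 1
    iR <- i0; while (iR < length(work) && work[iR] > half) iR <- iR + 1
    fwhm <- max(f[iR] - f[iL], 1e-3)
    wid <- min(max(fwhm / 2.355, 0.5), 12)
    ctr <- f[i0]
    # local Gaussian least-squares refinement
    win <- abs(f - ctr) <= 3 * wid
    if (sum(win) >= 5) {
      opt <- try(stats::optim(c(ctr, h, wid), function(th) {
        g <- th[2] * exp(-(f[win] - th[1])^2 / (2 * th[3]^2))
        sum((work[win] - g)^2)
      }, method = "L-BFGS-B",
        lower = c(ctr - wid, 0.5 * h, 0.5), upper = c(ctr + wid, 1.5 * h, 12)),
        silent = TRUE)
      if (!inherits(opt, "try-error")) {
        ctr <- opt$par[1]; h <- opt$par[2]; wid <- opt$par[3]
      }
    }
    peaks <- rbind(peaks, data.frame(center = ctr, height = h, width = wid))
    work <- work - h * exp(-(f - ctr)^2 / (2 * wid^2))
  }
  # aperiodic refit on the peak-subtracted spectrum
  peak_model <- rep(0, length(f))
  for (j in seq_len(nrow(peaks))) {
    peak_model <- peak_model + peaks$height[j] *
      exp(-(f - peaks$center[j])^2 / (2 * peaks$width[j]^2))
  }
  co <- line_fit(lp - peak_model)
  model <- co[1] + co[2] * lf + peak_model
  r2 <- 1 - sum((lp - model)^2) / sum((lp - mean(lp))^2)

  alpha_pk <- peaks[peaks$center >= 8 & peaks$center <= 13, , drop = FALSE]
  if (nrow(alpha_pk) > 0) {
    paf <- alpha_pk$center[which.max(alpha_pk$height)]
    from_peak <- TRUE
  } else {
    flat2 <- lp - (co[1] + co[2] * lf)
    ia <- which(f >= 8 & f <= 13)
    paf <- f[ia][which.max(flat2[ia])]
    from_peak <- FALSE
  }
  structure(list(exponent = unname(-co[2]), offset = unname(co[1]),
                 peaks = peaks, paf = paf, paf_from_peak = from_peak,
                 fit_range = fit_range, r_squared = r2),
            class = "aperiodic_fit")
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf("<aperiodic_fit> exponent %.3f, offset %.3f, %d peak(s), PAF %.2f Hz (%s), R2 %.3f\n",
              x$exponent, x$offset, nrow(x$peaks), x$paf,
              if (x$paf_from_peak) "peak" else "fallback", x$r_squared))
  invisible(x)
}

#' Aperiodic fits for every patch plus the patch-average spectrum
#'
#' @param se a [spectral_estimate()]
#' @param ... passed to [fit_aperiodic()]
#' @return list with `exponents` (named, one per patch), `paf` (named, one
#'   per patch plus `"global"`), and `fits` (per-patch `aperiodic_fit`s)
#' @export
aperiodic_features <- function(se, ...) {
  P <- nrow(se$psd)
  fits <- lapply(seq_len(P), function(p) fit_aperiodic(se$freqs, se$psd[p, ], ...))
  gfit <- fit_aperiodic(se$freqs, colMeans(se$psd), ...)
  exponents <- stats::setNames(vapply(fits, `[[`, 0, "exponent"),
                               se$patch_labels)
  paf <- stats::setNames(c(vapply(fits, `[[`, 0, "paf"), gfit$paf),
                         c(se$patch_labels, "global"))
  list(exponents = exponents, paf = paf, fits = fits, global_fit = gfit)
}
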