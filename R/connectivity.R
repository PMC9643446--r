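# Pairwise functional connectivity on the cortical patches: coherence,
# imaginary coherence, phase locking value, weighted phase lag index and
# orthogonalized power envelope correlations, plus the collapse of the
# 68 x 68 patch matrices to 76 region-level connections.

#' Tapered cross-spectral ensemble of an epoched recording
#'
#' Per-epoch, per-DPSS-taper Fourier transforms retained as an ensemble so
#' that each estimator can apply its own averaging. Frequencies are
#' restricted to `[f_min, f_max]`.
#'
#' @param er an [epoched_recording()] with at least 2 epochs
#' @param half_bandwidth taper half-bandwidth in Hz (default 1)
#' @param f_min,f_max retained frequency range (default 1.25-48 Hz)
#' @return object of class `cross_spectra`: list with `X` (complex array,
#'   ensemble-units x patches x freqs), `freqs`, `n_epochs`, `n_tapers`
#' @export
cross_spectra <- function(er, half_bandwidth = 1, f_min = 1.25, f_max = 48) {
  ne <- n_epochs(er)
  if (ne < 2) stop("connectivity estimators need at least 2 epochs")
  spe <- dim(er$epochs)[3]
  P <- dim(er$epochs)[2]
  nw <- half_bandwidth * er$epoch_len_s
  k <- max(1, floor(2 * nw - 1))
  V <- dpss_tapers(spe, nw, k)
  freqs_all <- (0:(spe %/% 2)) * er$fs / spe
  sel <- which(freqs_all >= f_min & freqs_all <= f_max)
  U <- ne * k
  X <- array(complex(real = 0), c(U, P, length(sel)))
  u <- 0
  for (e in seq_len(ne)) {
    ep <- matrix(er$epochs[e, , ], nrow = P)    # patches x samples
    tep <- t(ep)
    for (j in seq_len(k)) {
      F <- stats::mvfft(tep * V[, j])
      u <- u + 1
      X[u, , ] <- t(F[sel, , drop = FALSE])
    }
  }
  structure(list(X = X, freqs = freqs_all[sel], n_epochs = ne, n_tapers = k,
                 patch_labels = er$patch_labels),
            class = "cross_spectra")
}

#' @export
print.cross_spectra <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf("<cross_spectra> %d ensemble units x %d patches x %d freqs (%g-%g Hz)\n",
              d[1], d[2], d[3], min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Coherence and imaginary coherence matrices per band
#'
#' Coherency `C(f) = <Sxy> / sqrt(<Sxx><Syy>)` over the epoch-taper
#' ensemble; the band value averages `|C(f)|` (coherence) and `|Im C(f)|`
#' (imaginary coherence, stored as magnitude so region averaging cannot
#' cancel signed contributions) over the band's frequencies.
#'
#' @param cs a [cross_spectra()]
#' @param bands a [band_set()]
#' @return list per band of lists with symmetric matrices `coh`, `imcoh`
#' @export
coherence_matrices <- function(cs, bands = band_set()) {
  P <- dim(cs$X)[2]
  nf <- dim(cs$X)[3]
  out <- lapply(bands, function(b) {
    idx <- which(cs$freqs >= b[1] & cs$freqs <= b[2])
    coh <- imc <- matrix(0, P, P)
    for (fi in idx) {
      Xf <- cs$X[, , fi]
      Pm <- Re(Xf); Qm <- Im(Xf)
      ReS <- crossprod(Pm) + crossprod(Qm)     # Re <Sxy> * U
      ImS <- crossprod(Qm, Pm) - crossprod(Pm, Qm)
      pw <- diag(ReS)
      if (any(pw <= 0)) stop("zero power at a band frequency")
      nrm <- sqrt(outer(pw, pw))
      coh <- coh + sqrt(ReS^2 + ImS^2) / nrm
      imc <- imc + abs(ImS) / nrm
    }
    lab <- cs$patch_labels
    coh <- coh / length(idx); imc <- imc / length(idx)
    dimnames(coh) <- dimnames(imc) <- list(lab, lab)
    list(coh = coh, imcoh = imc)
  })
  out
}

#' Weighted phase lag index matrices per band
#'
#' Vinck-style estimator without debiasing: per frequency
#' `|<Im Sxy>| / <|Im Sxy|>` over the epoch-taper ensemble (0/0 defined as
#' 0), averaged over the band's frequencies.
#'
#' @param cs a [cross_spectra()]
#' @param bands a [band_set()]
#' @return list per band of symmetric patches x patches matrices
#' @export
wpli_matrices <- function(cs, bands = band_set()) {
  P <- dim(cs$X)[2]
  U <- dim(cs$X)[1]
  ut <- which(upper.tri(matrix(0, P, P)))
  jj <- ((ut - 1) %/% P) + 1    # column index = y
  ii <- ((ut - 1) %% P) + 1     # row index = x
  lapply(bands, function(b) {
    idx <- which(cs$freqs >= b[1] & cs$freqs <= b[2])
    acc <- numeric(length(ut))
    for (fi in idx) {
      Xf <- cs$X[, , fi]
      Pm <- Re(Xf); Qm <- Im(Xf)
      # Im Sxy per unit for all upper-tri pairs, U x n_pairs
      E <- Qm[, ii, drop = FALSE] * Pm[, jj, drop = FALSE] -
           Pm[, ii, drop = FALSE] * Qm[, jj, drop = FALSE]
      num <- abs(colSums(E))
      den <- colSums(abs(E))
      w <- ifelse(den > 0, num / den, 0)
      acc <- acc + w
    }
    M <- matrix(0, P, P, dimnames = list(cs$patch_labels, cs$patch_labels))
    M[ut] <- acc / length(idx)
    M + t(M)
  })
}

# analytic band signals of all patches on the concatenated recording:
# list per band of complex samples x patches matrices
analytic_band_signals <- function(er, bands = band_set(), trim_s = 0.5) {
  x <- concat_epochs(er)
  tr <- round(trim_s * er$fs)
  n <- nrow(x)
  keep <- (tr + 1):(n - tr)
  lapply(bands, function(b) {
    analytic_band(x, er$fs, b[1], b[2])[keep, , drop = FALSE]
  })
}

#' Phase locking value matrices per band
#'
#' `PLV = |mean over samples of exp(i(phi_x - phi_y))|` on the concatenated
#' band-filtered analytic signals.
#'
#' @param Z complex samples x patches matrix of analytic band signals (one
#'   band), e.g. one element of the list built by the feature extractor, or
#'   an [epoched_recording()] (then `band` selects the band)
#' @param band band name or `c(lo, hi)` when `Z` is a recording
#' @return symmetric patches x patches PLV matrix
#' @export
plv_matrix <- function(Z, band = "alpha") {
  if (inherits(Z, "epoched_recording")) {
    if (is.character(band)) band <- band_set()[[band]]
    er <- Z
    x <- concat_epochs(er)
    tr <- round(0.5 * er$fs)
    Z <- analytic_band(x, er$fs, band[1], band[2])[(tr + 1):(nrow(x) - tr), ,
                                                   drop = FALSE]
  }
  n <- nrow(Z)
  A <- Mod(Z)
  A[A == 0] <- 1
  C <- Re(Z) / A
  S <- Im(Z) / A
  ReP <- crossprod(C) + crossprod(S)
  ImP <- crossprod(S, C) - crossprod(C, S)
  M <- sqrt(ReP^2 + ImP^2) / n
  diag(M) <- 1
  M
}

#' Orthogonalized power envelope correlation matrices
#'
#' For each ordered pair, the second signal is orthogonalized to the first
#' sample-wise (`y_perp = Im(y_a * conj(x_a)/|x_a|)`), squared envelopes are
#' block-averaged to an envelope sampling rate of `env_fs` and
#' log-transformed, and the log envelope of `x` is Pearson-correlated with
#' that of `y_perp`; the two directed values are averaged. A pair whose
#' orthogonalized residual is degenerate (e.g. `y` proportional to `x`)
#' gets 0. Envelope co-modulation is a slow phenomenon, so squared
#' envelopes are averaged down to a few hertz before the log-correlation;
#' this also suppresses phase-interference noise in the orthogonalized
#' residual.
#'
#' @param Z complex samples x patches matrix of analytic band signals
#' @param fs sampling rate of `Z`
#' @param env_fs envelope sampling rate after block averaging (default 4)
#' @param eps amplitude floor before the log
#' @return symmetric patches x patches PEC matrix
#' @export
pec_matrix <- function(Z, fs, env_fs = 4, eps = 1e-12) {
  n0 <- nrow(Z)
  P <- ncol(Z)
  w <- max(1, round(fs / env_fs))
  nb <- n0 %/% w
  n <- nb * w
  Zt <- Z[seq_len(n), , drop = FALSE]
  blockmean <- function(M) {
    dim(M) <- c(w, nb, ncol(M))
    colMeans(M)                      # nb x P
  }
  lx <- log(blockmean(Mod(Zt)^2) + eps)
  lx_c <- sweep(lx, 2, colMeans(lx))
  lx_sd <- sqrt(colSums(lx_c^2))
  R <- Re(Zt); I <- Im(Zt)
  A <- Mod(Zt); A[A == 0] <- eps
  out <- matrix(0, P, P)
  for (x in seq_len(P)) {
    cx <- R[, x] / A[, x]
    sx <- I[, x] / A[, x]
    # y orthogonalized to x, all y at once: Im(y_a * conj(x_a)/|x_a|)
    Yp <- I * cx - R * sx
    ly <- log(blockmean(Yp^2) + eps)
    ly_c <- sweep(ly, 2, colMeans(ly))
    ly_sd <- sqrt(colSums(ly_c^2))
    num <- colSums(lx_c[, x] * ly_c)
    den <- lx_sd[x] * ly_sd
    r <- ifelse(den > sqrt(.Machine$double.eps), num / den, 0)
    # degenerate orthogonalized envelope (constant at the floor) -> 0
    r[ly_sd < 1e-8 * nb] <- 0
    out[x, ] <- r
  }
  M <- (out + t(out)) / 2
  diag(M) <- 0
  dimnames(M) <- dimnames(Z)[c(2, 2)]
  M
}

#' All five connectivity measures for every band
#'
#' @param er an [epoched_recording()]
#' @param bands a [band_set()]
#' @param half_bandwidth taper half-bandwidth for the spectral measures
#' @return nested list `result[[measure]][[band]]` of symmetric matrices,
#'   measures `coh`, `imcoh`, `plv`, `wpli`, `pec`
#' @export
connectivity_matrices <- function(er, bands = band_set(),
                                  half_bandwidth = 1) {
  cs <- cross_spectra(er, half_bandwidth,
                      f_min = band_range(bands)[1],
                      f_max = band_range(bands)[2])
  ci <- coherence_matrices(cs, bands)
  wp <- wpli_matrices(cs, bands)
  Zs <- analytic_band_signals(er, bands)
  lab <- er$patch_labels
  plv <- lapply(Zs, function(Z) {
    M <- plv_matrix(Z); dimnames(M) <- list(lab, lab); M
  })
  pec <- lapply(Zs, function(Z) {
    M <- pec_matrix(Z, er$fs); dimnames(M) <- list(lab, lab); M
  })
  list(coh = lapply(ci, `[[`, "coh"),
       imcoh = lapply(ci, `[[`, "imcoh"),
       plv = plv, wpli = wp, pec = pec)
}

#' Pairwise connectivity between two signals
#'
#' Convenience wrapper computing one measure for a single signal pair,
#' mirroring the full-matrix estimators exactly.
#'
#' @param x,y numeric vectors (same length)
#' @param fs sampling rate
#' @param measure one of `coh`, `imcoh`, `plv`, `wpli`, `pec`
#' @param band `c(lo, hi)` Hz or band name
#' @param epoch_len_s epoch length for ensemble-based measures
#' @return scalar connectivity value
#' @export
connectivity_pair <- function(x, y, fs, measure = "plv", band = "alpha",
                              epoch_len_s = 4) {
  if (is.character(band)) band <- band_set()[[band]]
  rec <- patch_recording(rbind(x, y), fs, c("x", "y"))
  er <- epoch_recording(rec, epoch_len_s)
  bands <- band_set(list(b = band))
  m <- connectivity_matrices(er, bands)[[measure]][[1]]
  m["x", "y"]
}

#' Collapse a patch connectivity matrix to region-level connections
#'
#' Inter-node values average all patch pairs between two region nodes;
#' intra-node values average all distinct unordered patch pairs within a
#' node (self-connections excluded). Single-patch nodes (the insular
#' nodes) have no intra-node value. The full 12-node scheme yields
#' 66 inter + 10 intra = 76 connections.
#'
#' @param cm symmetric patches x patches matrix with patch-label dimnames
#' @param scheme a [region_scheme()]
#' @return named numeric vector of region connections, names like
#'   `"frontal-lh|parietal-rh"` (inter) and `"frontal-lh|frontal-lh"` (intra)
#' @export
collapse_regions <- function(cm, scheme) {
  nodes <- attr(scheme, "nodes")
  members <- lapply(nodes, function(nd) scheme$patch[scheme$node == nd])
  names(members) <- nodes
  out <- numeric(0)
  nn <- length(nodes)
  for (a in seq_len(nn)) {
    for (b in a:nn) {
      pa <- members[[a]]; pb <- members[[b]]
      if (a == b) {
        if (length(pa) < 2) next               # single-patch node: no intra
        sub <- cm[pa, pa, drop = FALSE]
        val <- mean(sub[upper.tri(sub)])
      } else {
        val <- mean(cm[pa, pb, drop = FALSE])
      }
      out[paste0(nodes[a], "|", nodes[b])] <- val
    }
  }
  out
}
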