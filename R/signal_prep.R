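# Signal preparation: band definitions, zero-phase filtering and resampling,
# epoching, minimum-duration enforcement, and polarity-aligned collapsing of
# vertex signals into patch signals.

#' Canonical frequency bands
#'
#' The five analysis bands: delta 1.25-4, theta 4-8, alpha 8-13, beta 13-30,
#' gamma 30-48 Hz. Bands tile the full analysis range 1.25-48 Hz.
#'
#' @param bands named list of `c(lo, hi)` pairs to override the default
#' @return object of class `band_set`: named list of numeric length-2 vectors
#' @export
band_set <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- list(delta = c(1.25, 4), theta = c(4, 8), alpha = c(8, 13),
                  beta = c(13, 30), gamma = c(30, 48))
  }
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2 || b[1] >= b[2]) stop("degenerate band: ", nm)
  }
  structure(bands, class = "band_set")
}

#' Full analysis frequency range of a band set
#' @param bands a [band_set()]
#' @return c(lo, hi) in Hz
#' @export
band_range <- function(bands) {
  c(min(vapply(bands, `[`, 0, 1)), max(vapply(bands, `[`, 0, 2)))
}

#' Band-pass, notch filter and resample a recording
#'
#' Zero-phase band-pass (raised-cosine transition bands, 25% of each edge)
#' plus a zero-phase notch, followed by polyphase resampling to `target_fs`.
#'
#' @param rec a [patch_recording()]
#' @param band_lo,band_hi pass-band edges in Hz (default 1-100)
#' @param notch notch centre frequency in Hz (default 50); `NA` disables
#' @param target_fs output sampling rate (default 500)
#' @return filtered, resampled [patch_recording()]
#' @export
preprocess <- function(rec, band_lo = 1, band_hi = 100, notch = 50,
                       target_fs = 500) {
  fs <- rec$fs
  if (band_lo >= band_hi) stop("band_lo must be below band_hi")
  if (2 * band_hi > target_fs) {
    stop("Nyquist violation: band_hi above target_fs/2")
  }
  if (2 * band_hi > fs) stop("Nyquist violation: band_hi above fs/2")
  x <- t(rec$data)                        # samples x patches
  n <- nrow(x)
  H <- band_response(n, fs, band_lo, band_hi)
  if (!is.na(notch) && notch < fs / 2) {
    H <- H * notch_response(n, fs, notch)
  }
  y <- apply_response(x, H)
  if (target_fs != fs) {
    r <- target_fs / fs
    pq <- .ratio_int(r)
    n_out <- round(n * r)
    y <- apply(y, 2, function(col) {
      out <- signal::resample(col, pq[1], pq[2])
      length(out) <- n_out                # pad/trim to the exact length
      out[is.na(out)] <- 0
      out
    })
  }
  patch_recording(t(y), target_fs, rec$patch_labels, rec$subject_id)
}

# smallest integer ratio p/q equal to r (rates are rational in practice)
.ratio_int <- function(r, max_den = 10000) {
  for (q in 1:max_den) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop("cannot express resampling ratio as a small integer fraction")
}

#' Split a recording into fixed-length non-overlapping epochs
#'
#' The trailing partial epoch is discarded; reassembling the epochs
#' reproduces the truncated signal exactly.
#'
#' @param rec a [patch_recording()]
#' @param epoch_len_s epoch length in seconds (default 4)
#' @return an [epoched_recording()]
#' @export
epoch_recording <- function(rec, epoch_len_s = 4) {
  spe <- round(epoch_len_s * rec$fs)
  n <- ncol(rec$data)
  n_ep <- n %/% spe
  if (n_ep < 1) {
    stop("recording shorter than one epoch (", epoch_len_s, " s)")
  }
  keep <- rec$data[, seq_len(n_ep * spe), drop = FALSE]
  # patches x (samples) -> epochs x patches x samples
  arr <- array(0, c(n_ep, nrow(keep), spe))
  for (e in seq_len(n_ep)) {
    arr[e, , ] <- keep[, ((e - 1) * spe + 1):(e * spe)]
  }
  epoched_recording(arr, rec$fs, epoch_len_s, rec$patch_labels,
                    rec$subject_id)
}

#' Enforce a minimum total duration of epoched data
#'
#' Subjects with less than `min_s` seconds of data are marked excluded.
#'
#' @param er an [epoched_recording()]
#' @param min_s minimum retained duration in seconds (default 120)
#' @return `er` unchanged if long enough, otherwise an object of class
#'   `excluded_recording` carrying the subject id and the available duration
#' @export
enforce_min_duration <- function(er, min_s = 120) {
  stopifnot(min_s >= 0)
  have <- n_epochs(er) * er$epoch_len_s
  if (have >= min_s) return(er)
  structure(list(subject_id = er$subject_id, duration_s = have,
                 required_s = min_s),
            class = "excluded_recording")
}

#' Is a recording excluded?
#' @param x object returned by [enforce_min_duration()]
#' @export
is_excluded <- function(x) inherits(x, "excluded_recording")

#' Collapse vertex-level signals into polarity-aligned patch signals
#'
#' Within each patch, vertices whose sign disagrees with the patch majority
#' are flipped (a pi phase shift for real signals) before averaging, so that
#' anti-phase vertices do not cancel. The majority is determined by the sign
#' of each vertex's correlation with the patch's first principal temporal
#' component; zero-correlation vertices are never flipped.
#'
#' @param vertex_signals numeric matrix, vertices x samples
#' @param patch_assignment character/factor vector mapping each vertex (row)
#'   to a patch label
#' @param fs sampling rate of the vertex signals
#' @param subject_id subject identifier
#' @return a [patch_recording()] with one row per patch, in the order of
#'   first appearance in `patch_assignment`
#' @export
collapse_vertices <- function(vertex_signals, patch_assignment, fs,
                              subject_id = "subject") {
  vertex_signals <- as.matrix(vertex_signals)
  if (nrow(vertex_signals) != length(patch_assignment)) {
    stop("one patch assignment per vertex required")
  }
  patches <- unique(as.character(patch_assignment))
  out <- matrix(0, length(patches), ncol(vertex_signals))
  for (i in seq_along(patches)) {
    idx <- which(patch_assignment == patches[i])
    if (length(idx) == 0) stop("empty patch: ", patches[i])
    V <- vertex_signals[idx, , drop = FALSE]
    if (length(idx) == 1) {
      out[i, ] <- V
      next
    }
    Vc <- V - rowMeans(V)
    sv <- svd(Vc, nu = 0, nv = 1)
    pc1 <- sv$v[, 1]
    co <- as.vector(Vc %*% pc1)           # proportional to correlation sign
    # canonical PC orientation: align with the pre-flip majority
    if (sum(co) < 0 || (sum(co) == 0 && co[1] < 0)) co <- -co
    sgn <- sign(co)
    maj <- sign(sum(sgn))
    if (maj == 0) maj <- 1
    flip <- sgn != 0 & sgn != maj
    V[flip, ] <- -V[flip, , drop = FALSE]
    out[i, ] <- colMeans(V)
  }
  patch_recording(out, fs, patches, subject_id)
}
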