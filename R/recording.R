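# S3 containers for patch-level recordings and epoched recordings.

#' Construct a patch recording
#'
#' A single subject's source-patch time series: a patches-by-samples numeric
#' matrix with its sampling rate and patch labels.
#'
#' @param data numeric matrix, patches x samples (amplitude, arbitrary units)
#' @param fs sampling rate in Hz
#' @param patch_labels character vector, one label per row
#' @param subject_id subject identifier
#' @return object of class `patch_recording`
#' @export
patch_recording <- function(data, fs, patch_labels, subject_id = "subject") {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data))) {
    stop("data must be a finite numeric matrix")
  }
  if (length(patch_labels) != nrow(data)) {
    stop("patch_labels length must equal nrow(data)")
  }
  if (anyDuplicated(patch_labels)) stop("patch labels must be unique")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  rownames(data) <- patch_labels
  structure(list(subject_id = subject_id, data = data, fs = fs,
                 patch_labels = as.character(patch_labels)),
            class = "patch_recording")
}

#' @export
print.patch_recording <- function(x, ...) {
  cat(sprintf("<patch_recording> %s: %d patches x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a [patch_recording()]
#' @return seconds
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$fs

#' Construct an epoched recording
#'
#' @param epochs numeric array, n_epochs x patches x samples_per_epoch
#' @param fs sampling rate Hz
#' @param epoch_len_s epoch length in seconds
#' @param patch_labels patch labels
#' @param subject_id subject identifier
#' @return object of class `epoched_recording`
#' @export
epoched_recording <- function(epochs, fs, epoch_len_s, patch_labels,
                              subject_id = "subject") {
  stopifnot(length(dim(epochs)) == 3)
  spe <- dim(epochs)[3]
  if (spe != round(epoch_len_s * fs)) {
    stop("samples per epoch must equal epoch_len_s * fs")
  }
  if (dim(epochs)[1] < 1) stop("need at least one epoch")
  if (anyNA(epochs)) stop("epochs contain NA")
  structure(list(subject_id = subject_id, epochs = epochs, fs = fs,
                 epoch_len_s = epoch_len_s,
                 patch_labels = as.character(patch_labels)),
            class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoched_recording> %s: %d epochs x %d patches x %d samples (%g s @ %g Hz)\n",
              x$subject_id, d[1], d[2], d[3], x$epoch_len_s, x$fs))
  invisible(x)
}

#' Number of epochs
#' @param er an [epoched_recording()]
#' @export
n_epochs <- function(er) dim(er$epochs)[1]

# Concatenate epochs back into a continuous samples x patches matrix
# (temporal order preserved).
concat_epochs <- function(er) {
  d <- dim(er$epochs)
  # epochs[e, p, s] -> samples x patches with epochs stacked in time
  out <- matrix(0, d[1] * d[3], d[2])
  perm <- aperm(er$epochs, c(3, 1, 2))   # s, e, p
  dim(perm) <- c(d[3] * d[1], d[2])
  perm
}
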