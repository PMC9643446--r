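# Shared fixtures: tiny recordings and synthetic feature tables built in
# code at test time.

# multi-patch recording of pure sinusoids (one frequency per patch)
sine_recording <- function(freqs, fs = 500, duration_s = 20, amp = 1,
                           labels = NULL) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  X <- t(sapply(freqs, function(f) amp * sin(2 * pi * f * t)))
  if (is.null(labels)) labels <- paste0("superiorfrontal-", c("lh", "rh"))[seq_along(freqs)]
  patch_recording(X, fs, labels[seq_along(freqs)])
}

# feature table with arbitrary values but valid metadata, for the
# screening / statistics / prediction layers (no signal processing needed)
toy_feature_table <- function(n_subjects = 20, n_per_family = 10,
                              families = c("power_abs", "dfa", "plv"),
                              seed = 1, group = NULL, ages = NULL) {
  set.seed(seed)
  p <- n_per_family * length(families)
  X <- matrix(rnorm(n_subjects * p), n_subjects, p)
  meta <- data.frame(
    family = rep(families, each = n_per_family),
    band = "alpha",
    unit = paste0("u", rep(seq_len(n_per_family), length(families))),
    stringsAsFactors = FALSE)
  colnames(X) <- paste(meta$family, meta$band, meta$unit, sep = ".")
  subj <- data.frame(
    subject_id = sprintf("s%02d", seq_len(n_subjects)),
    group = group %||% rep(c("CON", "ASD"), length.out = n_subjects),
    age = ages %||% runif(n_subjects, 18, 55),
    stringsAsFactors = FALSE)
  rownames(X) <- subj$subject_id
  structure(list(values = X, col_meta = meta, subjects = subj),
            class = "feature_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small spectral_estimate built directly (no signal needed)
flat_spectrum <- function(p = 1, fmax = 60, df = 0.25, value = 1) {
  freqs <- seq(0, fmax, by = df)
  structure(list(freqs = freqs,
                 psd = matrix(value, p, length(freqs)),
                 n_epochs = 1, half_bandwidth = 1, n_tapers = 1,
                 patch_labels = dk_labels()[seq_len(p)]),
            class = "spectral_estimate")
}
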