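# Synthetic-cohort generator: patch-level EEG-like recordings with a
# power-law (1/f^chi) background, band-limited oscillations with
# controllable spectral peaks, amplitude envelopes carrying long-range
# temporal correlations (fractional Gaussian noise), controllable pairwise
# coupling, and cohort metadata with injectable age trends and group
# effects. Every subject's generator parameters are stored as ground truth
# so that downstream estimators can be validated.

#' Synthetic cohort configuration
#'
#' Builds the full recipe for a reproducible synthetic cohort. Defaults
#' emulate a two-group adult cohort (91 comparison, 95 autistic subjects;
#' ages truncated-normal on 18-55 years with group means 32.34 (SD 12.25)
#' and 43.65 (SD 8.99); AQ and sensory-perception-quotient scores with the
#' corresponding group moments) recorded for 300 s at 500 Hz over the 68
#' Desikan-Killiany patches.
#'
#' Signal structure per patch: a 1/f^chi Gaussian background plus one
#' band-limited oscillator per band, each oscillator amplitude-modulated by
#' a fractional-Gaussian-noise envelope whose Hurst parameter sets the
#' band's target DFA exponent. Coupled patch pairs share a common band
#' oscillator mixed with weight `kappa` at a fixed phase lag.
#'
#' @param seed integer seed; identical configs generate identical cohorts
#' @param n_con,n_asd group sizes
#' @param duration_s recording duration per subject, seconds
#' @param fs sampling rate, Hz
#' @param n_patches even number of patches (homotopic subset of the 68)
#' @param chi per-group aperiodic exponent, `list(con = c(mean, sd), asd = ...)`
#' @param background_sd standard deviation of the 1/f background
#' @param osc list per band: `c(center, bw, amplitude, amplitude_sd)` —
#'   oscillator centre frequency (Hz), spectral width (Hz), mean amplitude
#'   and between-subject amplitude SD (amplitudes truncated at 0)
#' @param alpha_center_sd between-subject SD of the alpha centre frequency
#' @param lrtc_target named per-band Hurst exponents in (0,1) for the
#'   oscillation envelopes; bands absent from the list get no slow envelope
#' @param lrtc_depth modulation depth of the fGn envelope (envelope =
#'   `max(eps, 1 + depth * fGn/sd(fGn))`)
#' @param coupling list of `list(i, j, band, lag, kappa)` couplings:
#'   patches `i` and `j` (labels or indices) share the band's oscillator
#'   with mixing weight `kappa` in `[0, 1]` and phase lag `lag` radians
#' @param age_model per-group age mean/sd, truncated to `age_range`
#' @param age_range inclusion window in years
#' @param age_slopes named per-parameter linear age slopes (per year,
#'   centred at 38 y); names as in `group_effect`
#' @param group_effect named Cohen's-d effects added to the ASD group's
#'   generator parameters. Supported names: `chi`, `alpha_center`,
#'   `amp_<band>` (oscillation amplitude) and `hurst_<band>`
#' @param sex_model per-group proportion of female subjects
#' @param questionnaire_model per-group AQ/SPQ moments
#' @param aq_signal_dependence optional `list(param = "amp_alpha", coef = x)`
#'   adding `coef * z(param)` to AQ
#' @return object of class `synth_config`
#' @export
synth_config <- function(seed = 1,
                         n_con = 91, n_asd = 95,
                         duration_s = 300, fs = 500, n_patches = 68,
                         chi = list(con = c(mean = 1.5, sd = 0.15),
                                    asd = c(mean = 1.5, sd = 0.15)),
                         background_sd = 1,
                         osc = list(
                           delta = c(center = 2.5,  bw = 1.0, amplitude = 0.20, amplitude_sd = 0.05),
                           theta = c(center = 6,    bw = 1.5, amplitude = 0.25, amplitude_sd = 0.06),
                           alpha = c(center = 10,   bw = 2.0, amplitude = 0.60, amplitude_sd = 0.15),
                           beta  = c(center = 20,   bw = 4.0, amplitude = 0.25, amplitude_sd = 0.06),
                           gamma = c(center = 38,   bw = 5.0, amplitude = 0.12, amplitude_sd = 0.03)),
                         alpha_center_sd = 0.5,
                         lrtc_target = c(delta = 0.6, theta = 0.6, alpha = 0.75,
                                         beta = 0.6, gamma = 0.6),
                         lrtc_depth = 0.6,
                         coupling = list(),
                         age_model = list(con = c(mean = 32.34, sd = 12.25),
                                          asd = c(mean = 43.65, sd = 8.99)),
                         age_range = c(18, 55),
                         age_slopes = c(),
                         group_effect = c(),
                         sex_model = c(con = 0.571, asd = 0.537),
                         questionnaire_model = list(
                           con = list(aq = c(50.97, 10.05), spq_vis = c(10.54, 2.98),
                                      spq_aud = c(9.13, 2.51)),
                           asd = list(aq = c(85.73, 9.88), spq_vis = c(7.07, 3.15),
                                      spq_aud = c(6.66, 2.51))),
                         aq_signal_dependence = NULL) {
  n_samp <- duration_s * fs
  if (abs(n_samp - round(n_samp)) > 1e-9) {
    stop("duration_s * fs must be an integer sample count")
  }
  if (n_con < 1 || n_asd < 1) stop("group sizes must be >= 1")
  for (h in lrtc_target) {
    if (!is.na(h) && (h <= 0 || h >= 1)) stop("Hurst parameters must lie in (0,1)")
  }
  for (cp in coupling) {
    if (cp$kappa < 0 || cp$kappa > 1) stop("coupling weight kappa must be in [0,1]")
  }
  for (g in chi) if (g["sd"] < 0) stop("sd must be >= 0")
  labels <- if (n_patches == 68) dk_labels() else dk_subset(n_patches)
  cfg <- list(seed = as.integer(seed), n_con = n_con, n_asd = n_asd,
              duration_s = duration_s, fs = fs, n_patches = n_patches,
              patch_labels = labels, chi = chi,
              background_sd = background_sd, osc = osc,
              alpha_center_sd = alpha_center_sd,
              lrtc_target = lrtc_target, lrtc_depth = lrtc_depth,
              coupling = coupling, age_model = age_model,
              age_range = age_range, age_slopes = age_slopes,
              group_effect = group_effect, sex_model = sex_model,
              questionnaire_model = questionnaire_model,
              aq_signal_dependence = aq_signal_dependence)
  class(cfg) <- "synth_config"
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> seed %d: %d CON + %d ASD, %g s @ %g Hz, %d patches\n",
              x$seed, x$n_con, x$n_asd, x$duration_s, x$fs, x$n_patches))
  invisible(x)
}

# Draw one subject's generator parameters (ground truth) from the config.
# Group effects (Cohen's d on the parameter's between-subject SD) and linear
# age slopes are applied to the parameter means before drawing.
draw_subject_params <- function(config, meta) {
  grp <- tolower(meta$group)
  eff <- function(name, base_sd) {
    d <- 0
    if (grp == "asd" && name %in% names(config$group_effect)) {
      d <- config$group_effect[[name]] * base_sd
    }
    a <- 0
    if (name %in% names(config$age_slopes)) {
      a <- config$age_slopes[[name]] * (meta$age - 38)
    }
    d + a
  }
  chi_m <- config$chi[[grp]]
  chi <- stats::rnorm(1, chi_m["mean"] + eff("chi", chi_m["sd"]), chi_m["sd"])
  chi <- max(chi, 0.1)
  bands <- names(config$osc)
  amps <- centers <- bws <- hursts <- stats::setNames(numeric(length(bands)), bands)
  for (b in bands) {
    o <- config$osc[[b]]
    amps[b] <- max(0, stats::rnorm(1, o["amplitude"] +
                                   eff(paste0("amp_", b), o["amplitude_sd"]),
                                   o["amplitude_sd"]))
    csd <- if (b == "alpha") config$alpha_center_sd else 0
    cshift <- if (b == "alpha") eff("alpha_center", max(csd, 1e-9)) else 0
    centers[b] <- stats::rnorm(1, o["center"] + cshift, csd)
    bws[b] <- o["bw"]
    h <- if (b %in% names(config$lrtc_target)) config$lrtc_target[[b]] else NA
    if (!is.na(h)) {
      h <- h + eff(paste0("hurst_", b), 0.05)
      h <- min(max(h, 0.05), 0.95)
    }
    hursts[b] <- h
  }
  list(chi = chi, amps = amps, centers = centers, bws = bws, hursts = hursts)
}

# fGn-derived positive amplitude envelope, linear in the fGn so that its
# Hurst exponent is preserved (a rectifying nonlinearity would not be).
lrtc_envelope <- function(n, hurst, depth, eps = 1e-6) {
  g <- fgn_davies_harte(n, hurst)
  pmax(eps, 1 + depth * g / stats::sd(g))
}

#' Generate one synthetic subject recording
#'
#' Each patch signal is a 1/f^chi background plus per-band oscillators;
#' bands with a Hurst target are amplitude-modulated by an fGn-derived
#' envelope; coupled patch pairs share a common band oscillator mixed with
#' weight kappa at the configured phase lag. Uses the current RNG state:
#' seed externally (or via [generate_cohort()]) for reproducibility.
#'
#' @param config a [synth_config()]
#' @param meta named list/row with at least `subject_id`, `group`, `age`
#' @param params optional pre-drawn generator parameters (ground truth);
#'   drawn from `config` if omitted
#' @return a [patch_recording()] with attribute `ground_truth`
#' @export
generate_subject <- function(config, meta, params = NULL) {
  if (!tolower(meta$group) %in% c("con", "asd")) stop("group must be CON or ASD")
  if (is.null(params)) params <- draw_subject_params(config, meta)
  n <- round(config$duration_s * config$fs)
  fs <- config$fs
  P <- config$n_patches
  labels <- config$patch_labels
  bands <- names(config$osc)

  # pre-generate shared oscillators for coupled pairs
  common <- list()
  for (k in seq_along(config$coupling)) {
    cp <- config$coupling[[k]]
    b <- cp$band
    common[[k]] <- phase_jitter_osc(n, fs, params$centers[b], params$bws[b])
  }

  X <- matrix(0, P, n)
  for (p in seq_len(P)) {
    sig <- powerlaw_noise(n, fs, params$chi, sd = config$background_sd)
    for (b in bands) {
      a <- params$amps[b]
      if (a <= 0) next
      osc <- phase_jitter_osc(n, fs, params$centers[b], params$bws[b])
      # mix in shared components for couplings involving this patch
      for (k in seq_along(config$coupling)) {
        cp <- config$coupling[[k]]
        if (cp$band != b) next
        ij <- c(cp$i, cp$j)
        if (is.character(ij)) ij <- match(ij, labels)
        if (!(p %in% ij)) next
        kap <- cp$kappa
        com <- common[[k]]
        if (p == ij[2] && cp$lag != 0) {
          com <- Re(analytic_signal(com) * exp(-1i * cp$lag))
        }
        osc <- sqrt(1 - kap^2) * osc + kap * com
      }
      h <- params$hursts[b]
      env <- if (!is.na(h)) lrtc_envelope(n, h, config$lrtc_depth) else 1
      sig <- sig + a * env * osc
    }
    X[p, ] <- sig
  }
  rec <- patch_recording(X, fs, labels, meta$subject_id)
  attr(rec, "ground_truth") <- params
  rec
}

#' Generate a full synthetic cohort
#'
#' Draws per-subject metadata (group, age, sex, AQ, SPQ scores) from the
#' configured distributions, then generates each subject's recording from a
#' per-subject seed derived from `config$seed`, so identical configurations
#' give bit-identical cohorts.
#'
#' @param config a [synth_config()]
#' @param return_recordings generate and return the recordings (`TRUE`), or
#'   only metadata, ground-truth parameters and per-subject seeds (`FALSE`;
#'   recordings can then be produced one at a time with
#'   [generate_cohort_subject()], keeping memory flat)
#' @return object of class `synth_cohort`: list with `config`, `meta`
#'   (data.frame, one row per subject, including per-subject seeds),
#'   `ground_truth` (list of per-subject generator parameters) and
#'   `recordings` (list of [patch_recording()] or `NULL`s)
#' @export
generate_cohort <- function(config, return_recordings = TRUE) {
  set.seed(config$seed)
  n <- config$n_con + config$n_asd
  group <- c(rep("CON", config$n_con), rep("ASD", config$n_asd))
  meta <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = group, stringsAsFactors = FALSE)
  meta$age <- NA_real_; meta$sex <- NA_character_
  meta$aq <- NA_real_; meta$spq_vis <- NA_real_; meta$spq_aud <- NA_real_
  for (g in c("CON", "ASD")) {
    idx <- which(group == g)
    gl <- tolower(g)
    am <- config$age_model[[gl]]
    meta$age[idx] <- rtruncnorm(length(idx), am["mean"], am["sd"],
                                config$age_range[1], config$age_range[2])
    meta$sex[idx] <- ifelse(stats::runif(length(idx)) < config$sex_model[[gl]],
                            "F", "M")
    qm <- config$questionnaire_model[[gl]]
    meta$aq[idx] <- stats::rnorm(length(idx), qm$aq[1], qm$aq[2])
    meta$spq_vis[idx] <- stats::rnorm(length(idx), qm$spq_vis[1], qm$spq_vis[2])
    meta$spq_aud[idx] <- stats::rnorm(length(idx), qm$spq_aud[1], qm$spq_aud[2])
  }
  meta$subject_seed <- sample.int(.Machine$integer.max - 1L, n)
  # ground-truth parameters drawn under each subject's own seed
  gt <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(meta$subject_seed[i])
    gt[[i]] <- draw_subject_params(config, meta[i, ])
  }
  # optional AQ dependence on a signal parameter
  dep <- config$aq_signal_dependence
  if (!is.null(dep)) {
    vals <- vapply(gt, function(p) param_lookup(p, dep$param), 0)
    z <- (vals - mean(vals)) / stats::sd(vals)
    meta$aq <- meta$aq + dep$coef * z
  }
  recs <- vector("list", n)
  if (return_recordings) {
    for (i in seq_len(n)) {
      set.seed(meta$subject_seed[i])
      draw_subject_params(config, meta[i, ])  # replay to keep stream aligned
      recs[[i]] <- generate_subject(config, meta[i, ], params = gt[[i]])
    }
  }
  structure(list(config = config, meta = meta, ground_truth = gt,
                 recordings = recs),
            class = "synth_cohort")
}

#' Generate (or re-generate) one subject of a cohort on demand
#' @param cohort a `synth_cohort` (possibly created with
#'   `return_recordings = FALSE`)
#' @param i subject index
#' @return a [patch_recording()]
#' @export
generate_cohort_subject <- function(cohort, i) {
  set.seed(cohort$meta$subject_seed[i])
  draw_subject_params(cohort$config, cohort$meta[i, ])
  generate_subject(cohort$config, cohort$meta[i, ],
                   params = cohort$ground_truth[[i]])
}

param_lookup <- function(params, name) {
  if (name == "chi") return(params$chi)
  if (startsWith(name, "amp_")) return(params$amps[sub("amp_", "", name)])
  if (startsWith(name, "hurst_")) return(params$hursts[sub("hurst_", "", name)])
  if (name == "alpha_center") return(params$centers["alpha"])
  stop("unknown generator parameter: ", name)
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> %d subjects (%d CON / %d ASD), %s recordings\n",
              nrow(x$meta), sum(x$meta$group == "CON"),
              sum(x$meta$group == "ASD"),
              if (is.null(x$recordings[[1]])) "no" else "with"))
  invisible(x)
}

#' Write a cohort to a plain-text container directory
#'
#' Layout: `config.json` (the serialized configuration), `metadata.tsv`
#' (one row per subject), `ground_truth.tsv`, and optionally one
#' `data/<subject_id>.tsv` per subject (samples x patches, tab-separated,
#' header row of patch labels).
#'
#' @param cohort a `synth_cohort`
#' @param path output directory (created if absent)
#' @param write_data write the raw per-subject signal matrices (large)
#' @return `path`, invisibly
#' @export
write_cohort <- function(cohort, path, write_data = FALSE) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cfg <- cohort$config
  cfg$patch_labels <- NULL
  jsonlite::write_json(unclass(cfg), file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(cohort$meta, file.path(path, "metadata.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  gtdf <- do.call(rbind, lapply(seq_along(cohort$ground_truth), function(i) {
    p <- cohort$ground_truth[[i]]
    data.frame(subject_id = cohort$meta$subject_id[i], chi = p$chi,
               t(p$amps), t(p$centers), t(p$hursts), check.names = FALSE)
  }))
  names(gtdf) <- c("subject_id", "chi",
                   paste0("amp_", names(cohort$ground_truth[[1]]$amps)),
                   paste0("center_", names(cohort$ground_truth[[1]]$centers)),
                   paste0("hurst_", names(cohort$ground_truth[[1]]$hursts)))
  utils::write.table(gtdf, file.path(path, "ground_truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (write_data) {
    dir.create(file.path(path, "data"), showWarnings = FALSE)
    for (i in seq_len(nrow(cohort$meta))) {
      rec <- cohort$recordings[[i]] %||% generate_cohort_subject(cohort, i)
      m <- t(rec$data)
      colnames(m) <- rec$patch_labels
      utils::write.table(signif(m, 7),
                         file.path(path, "data",
                                   paste0(rec$subject_id, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  invisible(path)
}

#' Read cohort metadata (and optionally recordings) from a container
#' @param path directory written by [write_cohort()]
#' @return a `synth_cohort`; recordings are loaded only if present on disk
#' @export
read_cohort <- function(path) {
  meta <- utils::read.table(file.path(path, "metadata.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  cfgl <- jsonlite::read_json(file.path(path, "config.json"),
                              simplifyVector = TRUE)
  cfg <- synth_config(seed = cfgl$seed, n_con = cfgl$n_con,
                      n_asd = cfgl$n_asd, duration_s = cfgl$duration_s,
                      fs = cfgl$fs, n_patches = cfgl$n_patches)
  n <- nrow(meta)
  recs <- vector("list", n)
  ddir <- file.path(path, "data")
  if (dir.exists(ddir)) {
    for (i in seq_len(n)) {
      f <- file.path(ddir, paste0(meta$subject_id[i], ".tsv"))
      if (file.exists(f)) {
        m <- as.matrix(utils::read.table(f, sep = "\t", header = TRUE,
                                         check.names = FALSE))
        recs[[i]] <- patch_recording(t(m), cfg$fs, colnames(m),
                                     meta$subject_id[i])
      }
    }
  }
  structure(list(config = cfg, meta = meta, ground_truth = NULL,
                 recordings = recs),
            class = "synth_cohort")
}
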