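# Per-subject feature extraction: runs every estimator family on one
# recording and returns a named feature vector plus column metadata. Under
# the default 68-patch configuration the battery has exactly 3443 features:
# 680 power (absolute + relative), 6 theta/beta ratios, 30 asymmetries,
# 69 peak alpha frequencies, 68 aperiodic exponents, 345 DFA, 345 fEI and
# 1900 region-level connectivity values (5 measures x 5 bands x 76
# connections).

#' Feature-extraction options
#'
#' @param bands a [band_set()]
#' @param epoch_len_s epoch length in seconds (default 4)
#' @param half_bandwidth multitaper half-bandwidth in Hz (default 1)
#' @param dfa_fit range `c(lo, hi)` of DFA window sizes in seconds
#' @param fei_window_s fEI window length in seconds (default 5)
#' @param aperiodic_range aperiodic fit range in Hz
#' @return list of options
#' @export
feature_options <- function(bands = band_set(), epoch_len_s = 4,
                            half_bandwidth = 1, dfa_fit = c(2, 20),
                            fei_window_s = 5, aperiodic_range = c(1.25, 48)) {
  list(bands = bands, epoch_len_s = epoch_len_s,
       half_bandwidth = half_bandwidth, dfa_fit = dfa_fit,
       fei_window_s = fei_window_s, aperiodic_range = aperiodic_range)
}

#' Extract the full biomarker battery from one recording
#'
#' @param rec a [patch_recording()] (or an already-epoched
#'   [epoched_recording()])
#' @param opts a [feature_options()]
#' @return list with `values` (named numeric vector) and `meta` (data.frame
#'   with columns `family`, `band`, `unit`, one row per feature, in the
#'   same order)
#' @export
extract_features <- function(rec, opts = feature_options()) {
  er <- if (inherits(rec, "epoched_recording")) rec
        else epoch_recording(rec, opts$epoch_len_s)
  scheme <- region_scheme(er$patch_labels)
  bands <- opts$bands
  bn <- names(bands)
  lab <- er$patch_labels

  vals <- numeric(0)
  meta <- list()
  add <- function(family, band, unit, v) {
    vals <<- c(vals, as.numeric(v))
    meta[[length(meta) + 1]] <<- data.frame(
      family = family, band = band, unit = unit, stringsAsFactors = FALSE)
  }

  # --- spectral ---
  se <- multitaper_psd(er, opts$half_bandwidth)
  bp <- band_power(se, bands)
  for (b in bn) {
    add("power_abs", b, lab, bp$absolute[, b])
    add("power_rel", b, lab, bp$relative[, b])
  }
  tbr <- theta_beta_ratio(bp, scheme)
  add("tbr", NA, names(tbr), tbr)
  asym <- power_asymmetry(bp, scheme)
  for (b in bn) add("asymmetry", b, rownames(asym), asym[, b])
  ap <- aperiodic_features(se, fit_range = opts$aperiodic_range)
  add("aperiodic", NA, names(ap$exponents), ap$exponents)
  add("paf", NA, names(ap$paf), ap$paf)

  # --- analytic band signals shared by criticality + plv/pec ---
  x <- concat_epochs(er)
  tr <- round(0.5 * er$fs)
  keep <- (tr + 1):(nrow(x) - tr)
  dfa_by_band <- fei_by_band <- list()
  Zs <- list()
  for (b in bn) {
    Z <- analytic_band(x, er$fs, bands[[b]][1], bands[[b]][2])[keep, ,
                                                               drop = FALSE]
    Zs[[b]] <- Z
    env <- Mod(Z)
    d_ex <- f_ex <- numeric(ncol(env))
    for (p in seq_len(ncol(env))) {
      d <- dfa(env[, p], fit_lo_s = opts$dfa_fit[1],
               fit_hi_s = opts$dfa_fit[2], fs = er$fs)
      d_ex[p] <- d$exponent
      f_ex[p] <- fei(env[, p], window_s = opts$fei_window_s,
                     dfa_exponent = d$exponent, fs = er$fs)$fei
    }
    dfa_by_band[[b]] <- d_ex
    fei_by_band[[b]] <- f_ex
  }
  # patch values plus the global average per band
  for (b in bn) add("dfa", b, c(lab, "global"),
                    c(dfa_by_band[[b]], mean(dfa_by_band[[b]])))
  for (b in bn) add("fei", b, c(lab, "global"),
                    c(fei_by_band[[b]], mean(fei_by_band[[b]])))

  # --- connectivity ---
  cs <- cross_spectra(er, opts$half_bandwidth,
                      f_min = band_range(bands)[1],
                      f_max = band_range(bands)[2])
  ci <- coherence_matrices(cs, bands)
  wp <- wpli_matrices(cs, bands)
  conn <- list(coh = lapply(ci, `[[`, "coh"),
               imcoh = lapply(ci, `[[`, "imcoh"),
               plv = lapply(Zs, function(Z) {
                 M <- plv_matrix(Z); dimnames(M) <- list(lab, lab); M
               }),
               wpli = wp,
               pec = lapply(Zs, function(Z) {
                 M <- pec_matrix(Z, er$fs); dimnames(M) <- list(lab, lab); M
               }))
  for (m in c("coh", "imcoh", "plv", "wpli", "pec")) {
    for (b in bn) {
      v <- collapse_regions(conn[[m]][[b]], scheme)
      add(m, b, names(v), v)
    }
  }

  meta <- do.call(rbind, meta)
  names(vals) <- paste(meta$family,
                       ifelse(is.na(meta$band), "none", meta$band),
                       meta$unit, sep = ".")
  list(values = vals, meta = meta)
}

#' Assemble per-subject feature outputs into a feature table
#'
#' Columns are ordered deterministically by (family, band, spatial unit)
#' and validated for completeness: a subject missing any column is an
#' error. Under the default configuration the table has exactly 3443
#' columns.
#'
#' @param feature_list list of [extract_features()] outputs, one per subject
#' @param meta data.frame of subject metadata (one row per subject; must
#'   contain `subject_id`)
#' @return object of class `feature_table`: list with `values`
#'   (subjects x features matrix), `col_meta` (family/band/unit per column)
#'   and `subjects` (the metadata)
#' @export
assemble_feature_table <- function(feature_list, meta) {
  stopifnot(length(feature_list) == nrow(meta))
  fam_order <- c("power_abs", "power_rel", "tbr", "asymmetry", "paf",
                 "aperiodic", "dfa", "fei", "coh", "imcoh", "plv", "wpli",
                 "pec")
  cm <- feature_list[[1]]$meta
  ord <- order(match(cm$family, fam_order),
               ifelse(is.na(cm$band), "", cm$band), cm$unit)
  cm <- cm[ord, ]
  ref_names <- names(feature_list[[1]]$values)[ord]
  X <- matrix(NA_real_, length(feature_list), length(ref_names))
  for (i in seq_along(feature_list)) {
    v <- feature_list[[i]]$values
    missing <- setdiff(ref_names, names(v))
    if (length(missing) > 0) {
      stop("subject ", meta$subject_id[i], " is missing feature(s): ",
           paste(utils::head(missing, 3), collapse = ", "))
    }
    X[i, ] <- v[ref_names]
  }
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1, ]
    stop("NA feature for subject ", meta$subject_id[bad[1]],
         " in column ", ref_names[bad[2]])
  }
  colnames(X) <- ref_names
  rownames(X) <- meta$subject_id
  rownames(cm) <- NULL
  structure(list(values = X, col_meta = cm, subjects = meta),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d features\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(feature_type(x))
  cat("  per type:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Feature type of each column
#'
#' The twelve statistical families used for within-type FDR control:
#' absolute and relative power pool into a single `power` type.
#' @param ft a [feature_table()]
#' @return character vector, one type per column
#' @export
feature_type <- function(ft) {
  fam <- ft$col_meta$family
  ifelse(fam %in% c("power_abs", "power_rel"), "power", fam)
}

#' Extract features for every subject of a synthetic cohort
#'
#' Recordings are generated (or re-generated) one at a time so that memory
#' stays flat for large cohorts.
#'
#' @param cohort a `synth_cohort`
#' @param opts a [feature_options()]
#' @param min_duration_s subjects with less data are excluded (default 0:
#'   synthetic recordings have a known duration)
#' @param progress print per-subject progress
#' @return a [feature_table()]
#' @export
extract_cohort_features <- function(cohort, opts = feature_options(),
                                    min_duration_s = 0, progress = FALSE) {
  n <- nrow(cohort$meta)
  fl <- vector("list", n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    rec <- cohort$recordings[[i]] %||% generate_cohort_subject(cohort, i)
    er <- epoch_recording(rec, opts$epoch_len_s)
    er2 <- enforce_min_duration(er, min_duration_s)
    if (is_excluded(er2)) {
      keep[i] <- FALSE
      next
    }
    fl[[i]] <- extract_features(er2, opts)
    keep[i] <- TRUE
    if (progress) {
      message(sprintf("  features %d/%d (%s)", i, n,
                      cohort$meta$subject_id[i]))
    }
  }
  assemble_feature_table(fl[keep], cohort$meta[keep, , drop = FALSE])
}

#' Write a feature table as TSV
#'
#' Three metadata header rows (family, band, unit) above the subject rows.
#' @param ft a [feature_table()]
#' @param path output file
#' @export
write_feature_table <- function(ft, path) {
  hdr <- rbind(c("family", ft$col_meta$family),
               c("band", ifelse(is.na(ft$col_meta$band), "none",
                                ft$col_meta$band)),
               c("unit", ft$col_meta$unit))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(hdr, 1, paste, collapse = "\t"), con)
  body <- cbind(rownames(ft$values),
                format(ft$values, digits = 8, trim = TRUE, scientific = TRUE))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Screen features for linear age effects
#'
#' Per feature: Pearson correlation with age and its two-sided t-test
#' p-value; Benjamini-Hochberg FDR within each of the twelve feature types;
#' a type is flagged when more than `flag_frac` of its features are
#' significant at `alpha` after correction. Flagged types are refined to
#' (family x band) subgroups by the same rule, and those subgroups are what
#' [detrend_age()] removes.
#'
#' @param ft a [feature_table()]
#' @param ages numeric vector (defaults to `ft$subjects$age`)
#' @param alpha significance level on adjusted p (default 0.05)
#' @param flag_frac flagging threshold on the significant fraction
#'   (default 0.05)
#' @return object of class `age_screen`: list with `per_feature`
#'   (data.frame: r, p, p_adj, type, flagged), `per_type` (data.frame:
#'   type, n, pct_significant, flagged) and `flagged_columns` (indices)
#' @export
age_screen <- function(ft, ages = ft$subjects$age, alpha = 0.05,
                       flag_frac = 0.05) {
  n <- nrow(ft$values)
  if (n < 3) stop("need at least 3 subjects")
  if (stats::sd(ages) == 0) stop("constant age vector")
  X <- ft$values
  a_c <- ages - mean(ages)
  X_c <- sweep(X, 2, colMeans(X))
  sx <- sqrt(colSums(X_c^2))
  r <- as.vector(crossprod(X_c, a_c)) / (sx * sqrt(sum(a_c^2)))
  r[sx == 0] <- 0
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  type <- feature_type(ft)
  p_adj <- rep(NA_real_, length(p))
  for (ty in unique(type)) {
    idx <- type == ty
    p_adj[idx] <- fdr_bh(p[idx])
  }
  sig <- p_adj < alpha
  per_type <- do.call(rbind, lapply(unique(type), function(ty) {
    idx <- type == ty
    data.frame(type = ty, n = sum(idx),
               pct_significant = 100 * mean(sig[idx]),
               flagged = mean(sig[idx]) > flag_frac,
               stringsAsFactors = FALSE)
  }))
  # refine flagged types to (family x band) subgroups
  flagged_cols <- logical(ncol(X))
  band <- ifelse(is.na(ft$col_meta$band), "none", ft$col_meta$band)
  sub_id <- paste(ft$col_meta$family, band)
  for (ty in per_type$type[per_type$flagged]) {
    idx <- which(type == ty)
    for (sg in unique(sub_id[idx])) {
      jdx <- idx[sub_id[idx] == sg]
      if (mean(sig[jdx]) > flag_frac) flagged_cols[jdx] <- TRUE
    }
  }
  structure(list(
    per_feature = data.frame(r = r, p = p, p_adj = p_adj, type = type,
                             flagged = flagged_cols),
    per_type = per_type,
    flagged_columns = which(flagged_cols)), class = "age_screen")
}

#' @export
print.age_screen <- function(x, ...) {
  cat("<age_screen> % significant per feature type:\n")
  for (i in seq_len(nrow(x$per_type))) {
    cat(sprintf("  %-10s %6.1f%%%s\n", x$per_type$type[i],
                x$per_type$pct_significant[i],
                if (x$per_type$flagged[i]) "  [flagged]" else ""))
  }
  invisible(x)
}

#' Remove linear age trends from flagged feature columns
#'
#' Each flagged column is replaced by its whole-cohort OLS residual (groups
#' pooled) plus the column's original mean; unflagged columns are
#' untouched. Idempotent up to numerical noise.
#'
#' @param ft a [feature_table()]
#' @param screen an [age_screen()] result (or integer column indices)
#' @param ages ages (defaults to `ft$subjects$age`)
#' @return a detrended [feature_table()]
#' @export
detrend_age <- function(ft, screen, ages = ft$subjects$age) {
  cols <- if (inherits(screen, "age_screen")) screen$flagged_columns
          else as.integer(screen)
  if (length(cols) == 0) return(ft)
  A <- cbind(1, ages)
  Y <- ft$values[, cols, drop = FALSE]
  co <- stats::lm.fit(A, Y)$coefficients
  resid <- Y - A %*% co
  ft$values[, cols] <- sweep(resid, 2, colMeans(Y), "+")
  ft
}
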