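test_that("identical configurations generate bit-identical subjects", {
  cfg <- synth_config(seed = 21, n_con = 1, n_asd = 1, duration_s = 20,
                      n_patches = 2)
  ch1 <- generate_cohort(cfg)
  ch2 <- generate_cohort(cfg)
  expect_identical(ch1$recordings[[1]]$data, ch2$recordings[[1]]$data)
  expect_identical(ch1$meta, ch2$meta)
  # on-demand regeneration reproduces the stored recording
  rec <- generate_cohort_subject(ch1, 2)
  expect_identical(rec$data, ch1$recordings[[2]]$data)
})

test_that("pure power-law configuration has a log-log linear spectrum", {
  cfg <- synth_config(seed = 22, n_con = 1, n_asd = 1, duration_s = 120,
                      n_patches = 2,
                      chi = list(con = c(mean = 2, sd = 0),
                                 asd = c(mean = 2, sd = 0)),
                      osc = list(alpha = c(center = 10, bw = 2,
                                           amplitude = 0, amplitude_sd = 0)))
  ch <- generate_cohort(cfg)
  se <- multitaper_psd(epoch_recording(ch$recordings[[1]], 4))
  sel <- se$freqs >= 1.25 & se$freqs <= 48
  fit <- lm(log10(colMeans(se$psd)[sel]) ~ log10(se$freqs[sel]))
  expect_equal(unname(coef(fit)[2]), -2, tolerance = 0.15)
})

test_that("a configured alpha peak appears at its centre frequency", {
  cfg <- synth_config(seed = 23, n_con = 1, n_asd = 1, duration_s = 120,
                      n_patches = 2, alpha_center_sd = 0,
                      osc = list(alpha = c(center = 10, bw = 2,
                                           amplitude = 0.8,
                                           amplitude_sd = 0)))
  ch <- generate_cohort(cfg)
  se <- multitaper_psd(epoch_recording(ch$recordings[[1]], 4))
  psd <- colMeans(se$psd)
  sel <- which(se$freqs >= 8 & se$freqs <= 13)
  # flatten against the aperiodic fit before locating the peak
  ap <- fit_aperiodic(se$freqs, psd)
  flat <- log10(psd[sel]) -
    (ap$offset - ap$exponent * log10(se$freqs[sel]))
  peak_f <- se$freqs[sel][which.max(flat)]
  expect_lt(abs(peak_f - 10), 0.5)
})

test_that("default cohort metadata matches the configured demographics", {
  cfg <- synth_config(seed = 24)
  ch <- generate_cohort(cfg, return_recordings = FALSE)
  expect_equal(sum(ch$meta$group == "CON"), 91)
  expect_equal(sum(ch$meta$group == "ASD"), 95)
  expect_true(all(ch$meta$age >= 18 & ch$meta$age <= 55))
  expect_true(all(is.finite(ch$meta$aq)))
  # group age means near the configured truncated-normal moments
  expect_equal(mean(ch$meta$age[ch$meta$group == "CON"]), 33.2,
               tolerance = 0.15)
  expect_gt(mean(ch$meta$age[ch$meta$group == "ASD"]),
            mean(ch$meta$age[ch$meta$group == "CON"]))
})

test_that("zero group effect leaves ground-truth parameters exchangeable", {
  ps <- sapply(1:20, function(s) {
    cfg <- synth_config(seed = 300 + s, n_con = 15, n_asd = 15,
                        duration_s = 4, n_patches = 2)
    ch <- generate_cohort(cfg, return_recordings = FALSE)
    amps <- vapply(ch$ground_truth, function(p) p$amps[["alpha"]], 0)
    t.test(amps[ch$meta$group == "CON"], amps[ch$meta$group == "ASD"])$p.value
  })
  expect_gte(sum(ps > 0.01), 19)   # at most one false positive at alpha=.01
})

test_that("an injected age slope on chi is recovered from ground truth", {
  cfg <- synth_config(seed = 26, n_con = 60, n_asd = 60, duration_s = 4,
                      n_patches = 2, age_slopes = c(chi = -0.01))
  ch <- generate_cohort(cfg, return_recordings = FALSE)
  chi <- vapply(ch$ground_truth, `[[`, 0, "chi")
  fit <- summary(lm(chi ~ ch$meta$age))
  est <- fit$coefficients[2, 1]
  se <- fit$coefficients[2, 2]
  expect_lt(abs(est - (-0.01)), 2 * se)
})

test_that("a d-scaled group effect shifts the ASD parameter mean", {
  cfg <- synth_config(seed = 27, n_con = 80, n_asd = 80, duration_s = 4,
                      n_patches = 2, group_effect = c(amp_alpha = 1.5))
  ch <- generate_cohort(cfg, return_recordings = FALSE)
  amps <- vapply(ch$ground_truth, function(p) p$amps[["alpha"]], 0)
  g <- ch$meta$group == "ASD"
  d_hat <- (mean(amps[g]) - mean(amps[!g])) /
    sqrt((var(amps[g]) + var(amps[!g])) / 2)
  expect_equal(d_hat, 1.5, tolerance = 0.5)
})

test_that("configuration validation rejects invalid parameters", {
  expect_error(synth_config(duration_s = 1.0005, fs = 500), "integer sample")
  expect_error(synth_config(lrtc_target = c(alpha = 1.2)), "Hurst")
  expect_error(synth_config(coupling = list(list(i = 1, j = 2,
    band = "alpha", lag = 0, kappa = 1.5))), "kappa")
  expect_error(generate_subject(synth_config(),
    list(subject_id = "x", group = "OTHER", age = 30)), "group")
})

test_that("cohort container round-trips metadata and data", {
  cfg <- synth_config(seed = 28, n_con = 2, n_asd = 1, duration_s = 8,
                      n_patches = 2)
  ch <- generate_cohort(cfg)
  dir <- tempfile("cohort")
  write_cohort(ch, dir, write_data = TRUE)
  back <- read_cohort(dir)
  expect_equal(back$meta$subject_id, ch$meta$subject_id)
  expect_equal(back$meta$age, ch$meta$age, tolerance = 1e-6)
  expect_equal(back$recordings[[1]]$data, ch$recordings[[1]]$data,
               tolerance = 1e-5, ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})
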