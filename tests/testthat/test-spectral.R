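test_that("multitaper PSD is Parseval-normalized on white noise", {
  set.seed(31)
  fs <- 250
  x <- rnorm(120 * fs)
  rec <- patch_recording(rbind(x), fs, "superiorfrontal-lh")
  se <- multitaper_psd(epoch_recording(rec, 4))
  integral <- sum(se$psd[1, ]) * (se$freqs[2] - se$freqs[1])
  expect_equal(integral, 1, tolerance = 0.05)
  expect_true(all(se$psd >= 0))
  expect_equal(se$n_tapers, 7)
})

test_that("a sinusoid's band power equals its time-domain variance", {
  fs <- 250
  A <- 2
  rec <- sine_recording(10, fs = fs, duration_s = 120, amp = A)
  se <- multitaper_psd(epoch_recording(rec, 4))
  df <- se$freqs[2] - se$freqs[1]
  band_p <- sum(se$psd[1, se$freqs >= 8 & se$freqs <= 13]) * df
  expect_equal(band_p, A^2 / 2, tolerance = 0.02 * A^2 / 2)
})

test_that("PSD averaging is idempotent over identical epochs", {
  set.seed(32)
  fs <- 100
  x <- rnorm(4 * fs)
  one <- epoched_recording(array(x, c(1, 1, 4 * fs)), fs, 4, "a")
  two <- epoched_recording(array(rep(x, each = 2), c(2, 1, 4 * fs)), fs, 4, "a")
  expect_equal(multitaper_psd(one)$psd, multitaper_psd(two)$psd)
})

test_that("DPSS tapers are orthonormal and cached", {
  V <- dpss_tapers(500, 4, 7)
  expect_equal(crossprod(V), diag(7), tolerance = 1e-8)
  expect_identical(V, dpss_tapers(500, 4, 7))   # cache hit
})

test_that("relative band powers follow bandwidth ratios on a flat PSD", {
  se <- flat_spectrum(p = 2)
  bp <- band_power(se)
  # alpha share of a flat spectrum = (13-8)/(48-1.25)
  expect_equal(unname(bp$relative[1, "alpha"]), (13 - 8) / (48 - 1.25),
               tolerance = 0.01)
  expect_equal(unname(rowSums(bp$relative)), c(1, 1), tolerance = 1e-12)
  expect_true(all(bp$relative >= 0 & bp$relative <= 1))
})

test_that("asymmetry is zero for identical hemispheres, linear in offsets,
           and antisymmetric under hemisphere swap", {
  labels <- dk_labels()
  scheme <- region_scheme(labels)
  se <- flat_spectrum(p = 68)
  bp <- band_power(se)
  asym <- power_asymmetry(bp, scheme)
  expect_equal(dim(asym), c(6, 5))
  expect_true(all(asym == 0))

  # right = left + c for every pair -> every region value = c
  bp2 <- bp
  bp2$absolute[35:68, ] <- bp2$absolute[35:68, ] + 0.7
  asym2 <- power_asymmetry(bp2, scheme)
  expect_equal(unname(asym2), matrix(0.7, 6, 5), tolerance = 1e-12)

  # swapping hemispheres negates the asymmetry
  bp3 <- bp
  set.seed(33)
  bp3$absolute[] <- rexp(68 * 5)
  bp3_sw <- bp3
  bp3_sw$absolute <- bp3$absolute[c(35:68, 1:34), ]
  rownames(bp3_sw$absolute) <- rownames(bp3$absolute)
  expect_equal(power_asymmetry(bp3_sw, scheme),
               -power_asymmetry(bp3, scheme), tolerance = 1e-12)
})

test_that("theta/beta ratio reduces to simple ratios and pools hemispheres", {
  scheme <- region_scheme(dk_labels())
  se <- flat_spectrum(p = 68)
  bp <- band_power(se)
  expect_equal(unname(theta_beta_ratio(bp, scheme)),
               rep((8 - 4) / (30 - 13), 6), tolerance = 1e-12)
  bp$absolute[, "theta"] <- 2 * bp$absolute[, "beta"]
  expect_equal(unname(theta_beta_ratio(bp, scheme)), rep(2, 6))
  expect_length(theta_beta_ratio(bp, scheme), 6)
})

test_that("aperiodic fit recovers a pure power law with a fallback PAF", {
  f <- seq(0.25, 60, by = 0.25)
  ap <- fit_aperiodic(f, f^-2)
  expect_equal(ap$exponent, 2, tolerance = 0.02)
  expect_false(ap$paf_from_peak)          # no peak above threshold
  expect_true(ap$paf >= 8 && ap$paf <= 13)
})

test_that("aperiodic fit separates a log-Gaussian alpha peak from the slope", {
  f <- seq(0.25, 60, by = 0.25)
  psd <- 10^(-1.5 * log10(f) + 0.6 * exp(-(f - 9.5)^2 / (2 * 1.1^2)))
  ap <- fit_aperiodic(f, psd)
  expect_equal(ap$exponent, 1.5, tolerance = 0.1)
  expect_equal(ap$paf, 9.5, tolerance = 0.1)
  expect_true(ap$paf_from_peak)
  expect_error(fit_aperiodic(f, psd - 1), "non-positive")
})

test_that("the region scheme covers all 68 patches with single-patch insula", {
  scheme <- region_scheme(dk_labels())
  expect_equal(nrow(scheme), 68)
  expect_equal(length(attr(scheme, "nodes")), 12)
  expect_equal(sum(scheme$node == "insular-lh"), 1)
  expect_equal(sum(scheme$node == "insular-rh"), 1)
  expect_equal(nrow(homotopic_pairs(scheme)), 34)
  expect_error(region_scheme(c("nonsense-lh")), "unknown")
})
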