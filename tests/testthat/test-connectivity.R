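# two-patch epoched recording from arbitrary signals
pair_er <- function(x, y, fs = 250, epoch_len_s = 4) {
  epoch_recording(patch_recording(rbind(x, y), fs, c("x", "y")), epoch_len_s)
}

test_that("coherence is 1 (imcoh 0) for a real-scaled copy and near chance
           for independent noise", {
  set.seed(51)
  fs <- 250
  x <- rnorm(60 * fs)
  er <- pair_er(x, 0.5 * x, fs)
  ci <- coherence_matrices(cross_spectra(er))
  for (b in names(ci)) {
    expect_equal(unname(ci[[b]]$coh["x", "y"]), 1, tolerance = 1e-6)
    expect_lt(ci[[b]]$imcoh["x", "y"], 1e-6)
  }
  er_ind <- pair_er(rnorm(300 * fs), rnorm(300 * fs), fs)
  ci2 <- coherence_matrices(cross_spectra(er_ind))
  for (b in names(ci2)) expect_lt(ci2[[b]]$coh["x", "y"], 0.2)
})

test_that("a quadrature (90 degree) pair has high imaginary coherence", {
  set.seed(52)
  fs <- 250
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- resteeg:::phase_jitter_osc(length(t), fs, 10, 1.5)
  xq <- Re(resteeg:::analytic_signal(x) * exp(-1i * pi / 2)) +
    rnorm(length(x), sd = 0.01)
  er <- pair_er(x, xq, fs)
  ci <- coherence_matrices(cross_spectra(er))$alpha
  expect_gt(ci$coh["x", "y"], 0.95)
  expect_gt(ci$imcoh["x", "y"], 0.9)
})

test_that("PLV is exact for identical and offset phases and matches the
           chance floor for random phases", {
  set.seed(53)
  n <- 50000
  ph <- cumsum(rnorm(n, 0.25, 0.05))
  Z1 <- exp(1i * ph)
  expect_equal(unname(plv_matrix(cbind(Z1, Z1))[1, 2]), 1, tolerance = 1e-12)
  expect_equal(unname(plv_matrix(cbind(Z1, Z1 * exp(1i * 1.1)))[1, 2]), 1,
               tolerance = 1e-12)
  # i.i.d. uniform phase differences: E|mean phasor| ~ sqrt(pi / (4 N))
  n2 <- 2000
  plvs <- replicate(200, {
    Zr <- exp(1i * runif(n2, 0, 2 * pi))
    unname(plv_matrix(cbind(Zr, rep(1 + 0i, n2)))[1, 2])
  })
  mc <- replicate(200, Mod(mean(exp(1i * runif(n2, 0, 2 * pi)))))
  expect_equal(mean(plvs), sqrt(pi / (4 * n2)), tolerance = 0.1)
  expect_equal(mean(plvs), mean(mc), tolerance = 0.1)
})

test_that("wPLI evaluates the Vinck formula with the 0/0 convention", {
  # hand-built ensemble: one frequency, Im Sxy = {+1, +1, -1} across units
  X <- array(complex(real = 0), c(3, 2, 1))
  X[, 1, 1] <- c(1, 1, 1)
  X[, 2, 1] <- c(-1i, -1i, 1i)      # Sxy = x*conj(y) = i, i, -i
  cs <- structure(list(X = X, freqs = 10, n_epochs = 3, n_tapers = 1,
                       patch_labels = c("x", "y")), class = "cross_spectra")
  w <- wpli_matrices(cs, band_set(list(alpha = c(8, 13))))$alpha
  expect_equal(unname(w["x", "y"]), 1 / 3, tolerance = 1e-12)

  # consistent lag: all Im positive -> 1
  X[, 2, 1] <- c(-1i, -2i, -0.5i)
  cs$X <- X
  w2 <- wpli_matrices(cs, band_set(list(alpha = c(8, 13))))$alpha
  expect_equal(unname(w2["x", "y"]), 1)

  # proportional signals (zero-lag): Im Sxy = 0 -> 0 by convention
  set.seed(54)
  x <- rnorm(40 * 250)
  w3 <- wpli_matrices(cross_spectra(pair_er(x, 2 * x)))$alpha
  expect_equal(unname(w3["x", "y"]), 0)
})

test_that("PEC removes shared zero-lag signal and detects shared envelopes", {
  set.seed(55)
  fs <- 250
  n <- 60 * fs
  # y proportional to x: orthogonalized residual is degenerate -> 0
  x <- resteeg:::phase_jitter_osc(n, fs, 10, 2)
  Z <- resteeg:::analytic_band(cbind(x, 0.7 * x), fs, 8, 13)
  expect_equal(unname(pec_matrix(Z, fs)[1, 2]), 0)

  # common slow envelope, independent phases -> clearly positive PEC
  n2 <- 120 * fs
  g <- resteeg:::fgn_davies_harte(n2, 0.75)
  slow <- resteeg:::apply_response(
    g, resteeg:::band_response(n2, fs, 0.001, 0.5, trans_frac = 1))
  env <- pmax(1 + 0.8 * slow / sd(slow), 0.05)
  a <- env * resteeg:::phase_jitter_osc(n2, fs, 10, 2)
  b <- env * resteeg:::phase_jitter_osc(n2, fs, 10, 2)
  Zab <- resteeg:::analytic_band(cbind(a, b), fs, 8, 13)
  expect_gt(pec_matrix(Zab, fs)[1, 2], 0.5)

  # independent signals -> |pec| small
  c1 <- resteeg:::phase_jitter_osc(n2, fs, 10, 2) *
    (1 + 0.5 * abs(resteeg:::fgn_davies_harte(n2, 0.7)))
  c2 <- resteeg:::phase_jitter_osc(n2, fs, 10, 2) *
    (1 + 0.5 * abs(resteeg:::fgn_davies_harte(n2, 0.7)))
  Zc <- resteeg:::analytic_band(cbind(c1, c2), fs, 8, 13)
  expect_lt(abs(pec_matrix(Zc, fs)[1, 2]), 0.1)
})

test_that("all measures are symmetric and amplitude-scale invariant", {
  set.seed(56)
  fs <- 250
  n <- 48 * fs
  x <- resteeg:::phase_jitter_osc(n, fs, 10, 2) + 0.3 * rnorm(n)
  y <- 0.5 * x + resteeg:::phase_jitter_osc(n, fs, 10, 2) + 0.3 * rnorm(n)
  m1 <- connectivity_matrices(pair_er(x, y, fs))
  m2 <- connectivity_matrices(pair_er(y, x, fs))       # swapped
  m3 <- connectivity_matrices(pair_er(3 * x, 0.2 * y, fs))  # rescaled
  for (meas in names(m1)) {
    v1 <- m1[[meas]]$alpha["x", "y"]
    expect_equal(v1, m2[[meas]]$alpha["y", "x"], tolerance = 1e-9)
    expect_equal(v1, m3[[meas]]$alpha["x", "y"], tolerance = 1e-6)
    expect_equal(m1[[meas]]$alpha, t(m1[[meas]]$alpha), tolerance = 1e-12)
  }
})

test_that("region collapse yields 76 named connections with correct
           averaging", {
  scheme <- region_scheme(dk_labels())
  P <- 68
  cm <- matrix(0.42, P, P, dimnames = list(dk_labels(), dk_labels()))
  v <- collapse_regions(cm, scheme)
  expect_length(v, 76)
  expect_true(all(v == 0.42))
  nm <- names(v)
  intra <- sum(sub("\\|.*", "", nm) == sub(".*\\|", "", nm))
  expect_equal(intra, 10)               # 12 nodes minus 2 single-patch insula
  expect_equal(length(v) - intra, 66)
  expect_false("insular-lh|insular-lh" %in% nm)
  expect_false("insular-rh|insular-rh" %in% nm)

  # a 2-patch node's intra value is that single pair's entry
  sub4 <- c("cuneus-lh", "lateraloccipital-lh", "cuneus-rh",
            "lateraloccipital-rh")
  sch4 <- region_scheme(sub4)
  cm4 <- matrix(0, 4, 4, dimnames = list(sub4, sub4))
  cm4["cuneus-lh", "lateraloccipital-lh"] <- 0.9
  cm4["lateraloccipital-lh", "cuneus-lh"] <- 0.9
  v4 <- collapse_regions(cm4, sch4)
  expect_equal(unname(v4["occipital-lh|occipital-lh"]), 0.9)
})

test_that("cross_spectra needs at least two epochs", {
  x <- rnorm(4 * 250)
  er1 <- epoch_recording(patch_recording(rbind(x, x), 250, c("a", "b")), 4)
  expect_error(cross_spectra(er1), "2 epochs")
})
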