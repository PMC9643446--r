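test_that("feature extraction respects the per-family count contract at
           reduced patch counts", {
  cfg <- synth_config(seed = 61, n_con = 1, n_asd = 1, duration_s = 60,
                      n_patches = 4)
  ch <- generate_cohort(cfg)
  fx <- extract_features(ch$recordings[[1]])
  fam <- table(fx$meta$family)
  P <- 4
  n_regions <- length(unique(region_scheme(ch$recordings[[1]]$patch_labels)$region))
  n_nodes <- length(attr(region_scheme(ch$recordings[[1]]$patch_labels),
                         "nodes"))
  expect_equal(unname(fam["power_abs"]), P * 5)
  expect_equal(unname(fam["power_rel"]), P * 5)
  expect_equal(unname(fam["tbr"]), n_regions)
  expect_equal(unname(fam["asymmetry"]), n_regions * 5)
  expect_equal(unname(fam["paf"]), P + 1)
  expect_equal(unname(fam["aperiodic"]), P)
  expect_equal(unname(fam["dfa"]), (P + 1) * 5)
  expect_equal(unname(fam["fei"]), (P + 1) * 5)
  # all four patches are single-patch region nodes: inter connections only
  n_conn <- choose(n_nodes, 2)
  for (m in c("coh", "imcoh", "plv", "wpli", "pec")) {
    expect_equal(unname(fam[m]), n_conn * 5)
  }
  expect_false(anyNA(fx$values))
})

test_that("assembly orders columns deterministically and is strict about
           missing features", {
  cfg <- synth_config(seed = 62, n_con = 2, n_asd = 1, duration_s = 60,
                      n_patches = 2)
  ch <- generate_cohort(cfg)
  fl <- lapply(ch$recordings, extract_features)
  ft <- assemble_feature_table(fl, ch$meta)
  expect_equal(nrow(ft$values), 3)
  # shuffling one subject's feature vector does not change the table
  fl2 <- fl
  perm <- sample(length(fl2[[2]]$values))
  fl2[[2]]$values <- fl2[[2]]$values[perm]
  fl2[[2]]$meta <- fl2[[2]]$meta[perm, ]
  ft2 <- assemble_feature_table(fl2, ch$meta)
  expect_identical(ft$values, ft2$values)
  # a missing column is an error naming the subject
  fl3 <- fl
  fl3[[3]]$values <- fl3[[3]]$values[-5]
  fl3[[3]]$meta <- fl3[[3]]$meta[-5, ]
  expect_error(assemble_feature_table(fl3, ch$meta), "sub-003")

  tsv <- tempfile(fileext = ".tsv")
  write_feature_table(ft, tsv)
  lines <- readLines(tsv)
  expect_equal(length(lines), 3 + 3)     # 3 metadata rows + 3 subjects
  unlink(tsv)
})

test_that("age screening flags a perfect linear trend at 100%", {
  ft <- toy_feature_table(n_subjects = 30, seed = 63)
  ages <- ft$subjects$age
  # make every dfa column a pure age trend
  idx <- which(ft$col_meta$family == "dfa")
  ft$values[, idx] <- 0.9 * ages + matrix(rnorm(30 * length(idx), sd = 0.01),
                                          30)
  sc <- age_screen(ft)
  row <- sc$per_type[sc$per_type$type == "dfa", ]
  expect_true(row$flagged)
  expect_equal(row$pct_significant, 100)
  expect_gt(abs(sc$per_feature$r[idx[1]]), 0.999)
  expect_lt(sc$per_feature$p[idx[1]], 1e-20)
  expect_true(all(sc$per_feature$p_adj >= sc$per_feature$p, na.rm = TRUE))
})

test_that("age screening stays quiet on age-independent features", {
  flags <- sapply(1:20, function(s) {
    ft <- toy_feature_table(n_subjects = 40, n_per_family = 30, seed = 700 + s)
    sum(age_screen(ft)$per_type$flagged)
  })
  expect_lte(mean(flags > 0), 0.25)     # flagged runs are rare
  expect_lte(sum(flags[1] > 0), 1)      # and small when they happen
})

test_that("detrending removes the linear age effect exactly and is
           idempotent", {
  ft <- toy_feature_table(n_subjects = 25, seed = 64)
  ages <- ft$subjects$age
  ft$values[, 1] <- 2.5 * ages + 7      # exact trend: residual is constant
  det <- detrend_age(ft, 1L)
  expect_equal(sd(det$values[, 1]), 0, tolerance = 1e-10)
  expect_equal(mean(det$values[, 1]), mean(ft$values[, 1]), tolerance = 1e-9)

  # noisy trend: OLS residuals are exactly uncorrelated with age
  ft$values[, 1] <- 2.5 * ages + 7 + rnorm(25, sd = 0.5)
  sc <- age_screen(ft)
  det2 <- detrend_age(ft, sc)
  for (j in sc$flagged_columns) {
    expect_lt(abs(cor(det2$values[, j], ages)), 1e-10)
  }
  det3 <- detrend_age(det2, sc)
  expect_equal(det2$values, det3$values, tolerance = 1e-12)
  # re-screening after detrending flags nothing among the treated columns
  if (length(sc$flagged_columns) > 0) {
    sc2 <- age_screen(det2)
    expect_equal(intersect(sc2$flagged_columns, sc$flagged_columns),
                 integer(0))
  }
  expect_error(age_screen(ft, ages = rep(30, 25)), "constant")
})
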