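test_that("mRMR picks the most relevant feature first and shuns duplicates", {
  set.seed(81)
  n <- 60
  y <- rep(c("A", "B"), each = n / 2)
  signal <- rnorm(n) + 2 * (y == "A")
  X <- cbind(best = signal,
             dup = signal,                           # exact duplicate
             weak = rnorm(n) + 0.5 * (y == "A"),
             noise1 = rnorm(n), noise2 = rnorm(n))
  expect_equal(mrmr_select(X, y, k = 1), 1L)
  sel2 <- mrmr_select(X, y, k = 2)
  expect_equal(sel2[1], 1L)
  expect_false(sel2[2] == 2L)            # duplicate penalized by redundancy
})

test_that("greedy mRMR matches exhaustive per-step objective maximization", {
  set.seed(82)
  n <- 80
  y <- rnorm(n)
  X <- matrix(rnorm(n * 6), n, 6)
  X[, 1] <- y + rnorm(n, sd = 0.5)
  X[, 2] <- y + rnorm(n, sd = 0.8)
  X[, 3] <- X[, 1] + rnorm(n, sd = 0.2)
  got <- mrmr_select(X, y, k = 4)

  # oracle: explicit greedy maximization of F / mean|r| at every step
  Fstat <- sapply(1:6, function(j) {
    r <- cor(X[, j], y); r^2 * (n - 2) / (1 - r^2)
  })
  sel <- which.max(Fstat)
  for (step in 2:4) {
    cand <- setdiff(1:6, sel)
    score <- sapply(cand, function(j) {
      red <- mean(abs(cor(X[, j], X[, sel, drop = FALSE])))
      Fstat[j] / red
    })
    sel <- c(sel, cand[which.max(score)])
  }
  expect_equal(got, sel)
})

test_that("balanced accuracy handles imbalance and the printed 4-sample case", {
  expect_equal(balanced_accuracy(c("a", "b", "a"), c("a", "b", "a")), 1)
  # constant single-class prediction scores 0.5 whatever the imbalance
  expect_equal(balanced_accuracy(c(rep("a", 9), "b"), rep("a", 10)), 0.5)
  expect_equal(balanced_accuracy(c("+", "+", "-", "-"),
                                 c("+", "-", "-", "-")), 0.75)
  expect_error(balanced_accuracy(rep("a", 4), rep("a", 4)), "two classes")
})

test_that("nMAE is 1 for the train-mean predictor and 0 for perfection", {
  expect_equal(nmae(c(0, 2), c(1, 1), train_mean = 1), 1)
  expect_equal(nmae(c(0, 2), c(0, 0), train_mean = 1), 1)
  expect_equal(nmae(c(3, 5, 9), c(3, 5, 9), train_mean = 2), 0)
  expect_error(nmae(c(1, 1), c(1, 1), train_mean = 1), "undefined")
})

test_that("the baseline signed-rank test matches exhaustive enumeration", {
  expect_equal(baseline_test(rep(0.5, 100), 0.5, "greater"), 1)
  set.seed(83)
  scores <- 0.5 + abs(rnorm(100, 0.05, 0.02))
  expect_lt(baseline_test(scores, 0.5, "greater"), 0.01)

  d <- c(1, 2, 3, 4, 5, -1)
  p <- baseline_test(0.5 + d, 0.5, "greater")
  # oracle: enumerate all 2^6 sign patterns on the average ranks
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 6))
  V_null <- as.matrix(signs) %*% r
  expect_equal(p, mean(V_null >= V_obs), tolerance = 1e-12)
})

test_that("model pipelines honour their selection contracts", {
  set.seed(84)
  n <- 40; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  y <- factor(rep(c("A", "B"), each = n / 2))
  X[, 1] <- X[, 1] + 3 * (y == "A")

  # extreme lasso shrinkage -> degenerate -> majority-class prediction
  obj <- resteeg:::fit_pipeline("logistic_l1", X, y, pool = 1:p,
                                hyper = list(C = 1e-7), classification = TRUE)
  expect_true(obj$degenerate)
  pr <- resteeg:::predict_pipeline(obj, X)
  expect_equal(length(unique(as.character(pr))), 1)

  # RFE halves the pool one feature per round
  sc <- resteeg:::scaler_fit(X)
  Xs <- resteeg:::scaler_apply(sc, X)
  keep <- resteeg:::rfe_select(Xs, y, C = 0.1, target = 4)
  expect_length(keep, 4)
  expect_true(1 %in% keep)               # the separating feature survives

  # forward selection never repeats a feature
  sel <- resteeg:::sfs_select(Xs, y, lambda = 0.05, max_steps = 6)
  expect_equal(anyDuplicated(sel), 0)
})

test_that("two-layer CV produces the full outer-fold bookkeeping without
           train/test overlap", {
  set.seed(85)
  n <- 24
  X <- matrix(rnorm(n * 12), n, 12)
  colnames(X) <- paste0("f", 1:12)
  y <- rep(c("A", "B"), each = n / 2)
  cv <- run_two_layer_cv(X, y, models = "logistic_l1",
                         grid = model_grid(mrmr_k = 4,
                                           logistic_C = c(0.1, 10)),
                         repeats = 3, outer_k = 4, inner_k = 3, seed = 85,
                         feature_types = NULL)
  expect_equal(nrow(cv$folds), 12)
  # every subject appears in exactly one test fold per repetition
  for (r in unique(cv$folds$rep)) {
    te <- unlist(strsplit(cv$folds$test_idx[cv$folds$rep == r], ";"))
    expect_setequal(as.integer(te), 1:n)
  }
  # stratification: class counts per fold within 1 of balance
  for (i in seq_len(nrow(cv$folds))) {
    idx <- as.integer(strsplit(cv$folds$test_idx[i], ";")[[1]])
    expect_lte(abs(sum(y[idx] == "A") - sum(y[idx] == "B")), 1)
  }
  # determinism
  cv2 <- run_two_layer_cv(X, y, models = "logistic_l1",
                          grid = model_grid(mrmr_k = 4,
                                            logistic_C = c(0.1, 10)),
                          repeats = 3, outer_k = 4, inner_k = 3, seed = 85,
                          feature_types = NULL)
  expect_identical(cv$folds, cv2$folds)
})

test_that("no information leaks from a fold's test subjects into its model", {
  set.seed(86)
  n <- 20
  X <- matrix(rnorm(n * 8), n, 8)
  colnames(X) <- paste0("f", 1:8)
  y <- rep(c("A", "B"), each = n / 2)
  args <- list(target = y, models = "logistic_l1",
               grid = model_grid(mrmr_k = 3, logistic_C = c(0.1, 10)),
               repeats = 1, outer_k = 4, inner_k = 3, seed = 86,
               feature_types = NULL)
  cv1 <- do.call(run_two_layer_cv, c(list(X), args))
  # perturb one subject wildly; folds with that subject in TEST must have
  # identical fitted pipelines (selection + hyperparameters)
  Xp <- X
  Xp[3, ] <- Xp[3, ] + 1000
  cv2 <- do.call(run_two_layer_cv, c(list(Xp), args))
  in_test <- vapply(strsplit(cv1$folds$test_idx, ";"),
                    function(s) "3" %in% s, TRUE)
  expect_true(any(in_test))
  expect_identical(cv1$folds$selected[in_test], cv2$folds$selected[in_test])
  expect_identical(cv1$folds$hyper[in_test], cv2$folds$hyper[in_test])
  expect_identical(cv1$folds$mrmr_k[in_test], cv2$folds$mrmr_k[in_test])
})

test_that("linearly separable classes reach near-perfect test accuracy and
           regression beats the mean baseline", {
  set.seed(87)
  n <- 40
  y <- rep(c("A", "B"), each = n / 2)
  X <- matrix(rnorm(n * 10), n, 10)
  X[y == "A", 1:3] <- X[y == "A", 1:3] + 4
  colnames(X) <- paste0("f", 1:10)
  cv <- run_two_layer_cv(X, y, models = "logistic_l1",
                         grid = reduced_grid(mrmr_k = 3, n_C = 4),
                         repeats = 2, outer_k = 5, inner_k = 3, seed = 87,
                         feature_types = NULL)
  expect_gte(cv$summary$test_mean, 0.95)

  yr <- rnorm(n)
  Xr <- cbind(yr + rnorm(n, sd = 0.2), matrix(rnorm(n * 5), n, 5))
  colnames(Xr) <- paste0("g", 1:6)
  cvr <- run_two_layer_cv(Xr, yr, models = "linear_l2",
                          grid = reduced_grid(mrmr_k = 3, n_C = 4),
                          repeats = 2, outer_k = 5, inner_k = 3, seed = 87,
                          feature_types = NULL)
  expect_lt(cvr$summary$test_mean, 0.6)   # nMAE well below the mean baseline
  expect_lt(cvr$summary$p_baseline, 0.05)
})

test_that("rf and svm pipelines run end to end on a small problem", {
  set.seed(88)
  n <- 30
  y <- rep(c("A", "B"), each = n / 2)
  X <- matrix(rnorm(n * 6), n, 6)
  X[, 2] <- X[, 2] + 2.5 * (y == "B")
  colnames(X) <- paste0("f", 1:6)
  cv <- run_two_layer_cv(X, y, models = c("rf", "svm"),
                         grid = model_grid(mrmr_k = 3, svm_C = c(0.05, 0.5),
                                           rf_trees = 50, rf_depth = 1:2),
                         repeats = 1, outer_k = 3, inner_k = 3, seed = 88,
                         feature_types = NULL)
  expect_equal(sort(unique(cv$folds$model)), c("rf", "svm"))
  expect_true(all(cv$summary$test_mean > 0.6))
})
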