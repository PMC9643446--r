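# Multivariate prediction: per-type mRMR feature selection, classifier and
# regressor pipelines, and the repeated stratified two-layer (nested)
# cross-validation framework with balanced accuracy / normalized MAE
# scoring and baseline significance tests.

#' Hyperparameter grids
#'
#' Defaults: mRMR k in {10, 20, 30, 40}; logistic-regression C on 16
#' log-spaced values in [0.01, 1000]; SVM C on 13 log-spaced values in
#' [0.001, 1]; random forest trees {10, 50, 100, 500, 1000} x depth {1, 2};
#' penalized linear regression mirrors the logistic grid.
#'
#' @param mrmr_k candidate numbers of mRMR-selected features per type
#' @param logistic_C,svm_C,linear_C regularization grids (C, inverse
#'   regularization strength)
#' @param rf_trees,rf_depth random-forest grids
#' @return object of class `model_grid`
#' @export
model_grid <- function(mrmr_k = c(10, 20, 30, 40),
                       logistic_C = 10^seq(log10(0.01), log10(1000),
                                           length.out = 16),
                       svm_C = 10^seq(log10(0.001), log10(1),
                                      length.out = 13),
                       linear_C = 10^seq(log10(0.01), log10(1000),
                                         length.out = 16),
                       rf_trees = c(10, 50, 100, 500, 1000),
                       rf_depth = c(1, 2)) {
  structure(list(mrmr_k = mrmr_k, logistic_C = logistic_C, svm_C = svm_C,
                 linear_C = linear_C, rf_trees = rf_trees,
                 rf_depth = rf_depth), class = "model_grid")
}

#' Reduced grids for small-sample runs
#' @param mrmr_k reduced mRMR grid
#' @param n_C number of regularization values kept (log-spaced subsets)
#' @return a [model_grid()]
#' @export
reduced_grid <- function(mrmr_k = c(5, 10), n_C = 6) {
  model_grid(mrmr_k = mrmr_k,
             logistic_C = 10^seq(log10(0.01), log10(1000), length.out = n_C),
             svm_C = 10^seq(log10(0.001), log10(1), length.out = n_C),
             linear_C = 10^seq(log10(0.01), log10(1000), length.out = n_C),
             rf_trees = c(50, 200), rf_depth = c(1, 2))
}

#' Minimal-redundancy-maximum-relevance feature selection
#'
#' Greedy forward selection: relevance is the F-statistic of each feature
#' against the target (one-way ANOVA F for class targets, the squared-t F
#' of the univariate regression for numeric targets); redundancy is the
#' mean absolute Pearson correlation with the already-selected features;
#' the next pick maximizes relevance/redundancy (quotient scheme). When
#' `type_labels` is given, selection runs within each feature type and the
#' union is returned (attenuating the imbalance in features per type).
#'
#' @param X numeric matrix (subjects x features)
#' @param y target (factor/character for classification, numeric for
#'   regression)
#' @param k number of features to select (per type)
#' @param type_labels optional per-column type labels
#' @return integer vector of selected column indices (for `type_labels`,
#'   ordered type by type; within a type, in selection order)
#' @export
mrmr_select <- function(X, y, k, type_labels = NULL) {
  stopifnot(k >= 1)
  if (is.null(type_labels)) {
    return(.mrmr_one(X, y, k, seq_len(ncol(X))))
  }
  out <- integer(0)
  for (ty in unique(type_labels)) {
    cols <- which(type_labels == ty)
    out <- c(out, .mrmr_one(X[, cols, drop = FALSE], y, k, cols))
  }
  out
}

.mrmr_one <- function(X, y, k, orig_idx) {
  rel <- relevance_f(X, y)
  usable <- which(is.finite(rel) & apply(X, 2, stats::sd) > 0)
  if (length(usable) == 0) return(integer(0))
  k <- min(k, length(usable))
  Xs <- scale(X[, usable, drop = FALSE])
  rel <- rel[usable]
  n <- nrow(Xs)
  sel <- integer(0)
  sum_absr <- numeric(length(usable))
  remaining <- seq_along(usable)
  first <- remaining[which.max(rel[remaining])]
  sel <- first
  remaining <- setdiff(remaining, first)
  while (length(sel) < k && length(remaining) > 0) {
    rnew <- abs(as.vector(crossprod(Xs[, remaining, drop = FALSE],
                                    Xs[, sel[length(sel)]]))) / (n - 1)
    sum_absr[remaining] <- sum_absr[remaining] + rnew
    red <- sum_absr[remaining] / length(sel)
    score <- rel[remaining] / pmax(red, .Machine$double.eps)
    nxt <- remaining[which.max(score)]
    sel <- c(sel, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  orig_idx[usable[sel]]
}

# univariate F-statistic of each column against the target
relevance_f <- function(X, y) {
  n <- nrow(X)
  if (is.numeric(y) && !is.factor(y)) {
    Xc <- sweep(X, 2, colMeans(X))
    yc <- y - mean(y)
    r <- as.vector(crossprod(Xc, yc)) /
      (sqrt(colSums(Xc^2)) * sqrt(sum(yc^2)))
    r[!is.finite(r)] <- 0
    return(r^2 * (n - 2) / pmax(1 - r^2, .Machine$double.eps))
  }
  y <- as.factor(y)
  k <- nlevels(y)
  gm <- rowsum(X, y) / as.vector(table(y))
  grand <- colMeans(X)
  ssb <- colSums(as.vector(table(y)) * sweep(gm, 2, grand)^2)
  ssw <- colSums(X^2) - colSums(as.vector(table(y)) * gm^2)
  (ssb / (k - 1)) / pmax(ssw / (n - k), .Machine$double.eps)
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity; 0.5 is chance for two classes
#' regardless of imbalance, and a constant single-class prediction scores
#' exactly 0.5.
#'
#' @param y_true,y_pred class labels (two classes present in `y_true`)
#' @return scalar in `[0, 1]`
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  classes <- sort(unique(y_true))
  if (length(classes) != 2) stop("balanced accuracy needs two classes in y_true")
  mean(vapply(classes, function(cl) {
    mean(y_pred[y_true == cl] == cl)
  }, 0))
}

#' Normalized mean absolute error
#'
#' Model MAE divided by the MAE of predicting the training-set mean;
#' 1 means no better than the mean, 0 is perfect.
#'
#' @param y_true,y_pred numeric vectors
#' @param train_mean mean of the training targets
#' @return scalar nMAE
#' @export
nmae <- function(y_true, y_pred, train_mean) {
  if (length(y_true) == 0) stop("empty vectors")
  den <- mean(abs(y_true - train_mean))
  if (den == 0) stop("nMAE undefined: targets constant at the training mean")
  mean(abs(y_true - y_pred)) / den
}

#' One-sided baseline test on cross-validation scores
#'
#' Wilcoxon signed-rank test of the outer-fold scores against the chance
#' baseline (0.5 for balanced accuracy, `greater`; 1.0 for nMAE, `less`).
#' All-zero differences give p = 1 by convention.
#'
#' @param scores numeric vector of fold scores (>= 6)
#' @param baseline 0.5 or 1.0
#' @param side `"greater"` or `"less"` (favorable direction)
#' @return p-value
#' @export
baseline_test <- function(scores, baseline = 0.5,
                          side = c("greater", "less")) {
  side <- match.arg(side)
  if (length(scores) < 6) stop("need at least 6 scores")
  d <- scores - baseline
  if (all(d == 0)) return(1)
  d <- d[d != 0]                       # standard zero handling
  if (side == "less") d <- -d
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  n <- length(d)
  if (n <= 14) {
    # exact tail by enumerating all sign patterns (handles ties via
    # average ranks)
    M <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vnull <- as.vector(M %*% r)
    return(mean(Vnull >= V - 1e-12))
  }
  mu <- n * (n + 1) / 4
  tie_corr <- sum(tapply(r, abs(d), length)^3 -
                  tapply(r, abs(d), length)) / 48
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - tie_corr
  stats::pnorm((V - mu) / sqrt(sig2), lower.tail = FALSE)
}

# ---- model pipelines -------------------------------------------------

# combos: data.frame of hyperparameter settings for one model, with a
# regularization rank used for parsimony tie-breaks (lower = stronger)
model_combos <- function(model, grid) {
  switch(model,
    logistic_l1 = ,
    logistic_l2 = data.frame(C = grid$logistic_C,
                             reg_rank = seq_along(grid$logistic_C)),
    svm = data.frame(C = grid$svm_C, reg_rank = seq_along(grid$svm_C)),
    rf = {
      g <- expand.grid(depth = grid$rf_depth, trees = grid$rf_trees)
      g$reg_rank <- order(order(g$depth, g$trees))
      g
    },
    linear_l1 = ,
    linear_l2 = data.frame(C = grid$linear_C,
                           reg_rank = seq_along(grid$linear_C)),
    stop("unknown model: ", model))
}

# glmnet requires >= 2 predictor columns; pad single-feature designs with
# an all-zero dummy (its coefficient is identically zero)
glmnet_fit <- function(x, y, ...) {
  pad <- ncol(x) < 2
  if (pad) x <- cbind(x, matrix(0, nrow(x), 2 - ncol(x)))
  # strong penalties legitimately return empty models (handled by the
  # degenerate-pipeline path); silence the convergence chatter
  fit <- suppressWarnings(glmnet::glmnet(x, y, ..., standardize = FALSE))
  attr(fit, "pad") <- pad
  fit
}
glmnet_predict <- function(fit, x, type) {
  if (isTRUE(attr(fit, "pad"))) x <- cbind(x, matrix(0, nrow(x), 1))
  stats::predict(fit, x, type = type)
}

# z-score parameters from a training matrix; constant columns get sd 1
scaler_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}
scaler_apply <- function(sc, X) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

# Fit one pipeline: standardization -> mRMR pool -> model-specific
# selection -> estimator. `pool` is the mRMR selection (column indices of
# X); classification targets must be factors with 2 levels.
fit_pipeline <- function(model, X, y, pool, hyper, classification,
                         sfs_max_steps = 20) {
  sc <- scaler_fit(X)
  Xs <- scaler_apply(sc, X)[, pool, drop = FALSE]
  n <- nrow(Xs)
  obj <- list(model = model, scaler = sc, pool = pool, hyper = hyper,
              classification = classification)
  if (classification) {
    obj$levels <- levels(y)
    obj$majority <- names(which.max(table(y)))
  } else {
    obj$train_mean <- mean(y)
  }
  if (model %in% c("logistic_l1", "logistic_l2", "linear_l1", "linear_l2")) {
    alpha <- if (grepl("l1", model)) 1 else 0
    family <- if (classification) "binomial" else "gaussian"
    lambda <- 1 / (n * hyper$C)
    keep <- seq_along(pool)
    if (model == "logistic_l2") {
      keep <- sfs_select(Xs, y, lambda, max_steps = sfs_max_steps)
    }
    fit <- glmnet_fit(Xs[, keep, drop = FALSE], y, family = family,
                      alpha = alpha, lambda = lambda)
    co <- as.matrix(stats::coef(fit))
    obj$degenerate <- all(abs(co[-1, 1]) < 1e-12)
    obj$fit <- fit
    obj$keep <- keep
  } else if (model == "svm") {
    keep <- rfe_select(Xs, y, hyper$C,
                       target = max(1, ceiling(length(pool) / 2)))
    fit <- e1071::svm(Xs[, keep, drop = FALSE], y, kernel = "linear",
                      cost = hyper$C, scale = FALSE,
                      type = "C-classification")
    obj$fit <- fit
    obj$keep <- keep
    obj$degenerate <- FALSE
  } else if (model == "rf") {
    fit <- randomForest::randomForest(Xs, y, ntree = hyper$trees,
                                      maxnodes = 2^hyper$depth)
    obj$fit <- fit
    obj$keep <- seq_along(pool)
    obj$degenerate <- FALSE
  } else stop("unknown model: ", model)
  class(obj) <- "resteeg_pipeline"
  obj
}

predict_pipeline <- function(obj, Xnew) {
  Xs <- scaler_apply(obj$scaler, Xnew)[, obj$pool, drop = FALSE]
  Xs <- Xs[, obj$keep, drop = FALSE]
  if (obj$classification && isTRUE(obj$degenerate)) {
    return(factor(rep(obj$majority, nrow(Xs)), levels = obj$levels))
  }
  if (obj$model %in% c("logistic_l1", "logistic_l2")) {
    pr <- glmnet_predict(obj$fit, Xs, type = "class")
    return(factor(as.character(pr), levels = obj$levels))
  }
  if (obj$model %in% c("linear_l1", "linear_l2")) {
    if (isTRUE(obj$degenerate)) return(rep(obj$train_mean, nrow(Xs)))
    return(as.numeric(glmnet_predict(obj$fit, Xs, type = "response")))
  }
  if (obj$model == "svm") {
    return(factor(as.character(stats::predict(obj$fit, Xs)),
                  levels = obj$levels))
  }
  if (obj$model == "rf") {
    return(stats::predict(obj$fit, Xs))
  }
  stop("unknown model")
}

# Sequential forward selection for the ridge-logistic pipeline: adds the
# feature whose ridge fit most improves 3-fold training-partition balanced
# accuracy; stops early when no candidate improves; never re-selects.
sfs_select <- function(Xs, y, lambda, max_steps = 20, inner_folds = 3) {
  p <- ncol(Xs)
  max_steps <- min(max_steps, p)
  folds <- make_folds(y, inner_folds, stratified = TRUE)
  score_set <- function(keep) {
    preds <- rep(NA_character_, length(y))
    for (f in seq_len(inner_folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2) return(0)
      fit <- glmnet_fit(Xs[tr, keep, drop = FALSE], y[tr],
                        family = "binomial", alpha = 0, lambda = lambda)
      preds[!tr] <- as.character(glmnet_predict(
        fit, Xs[!tr, keep, drop = FALSE], type = "class"))
    }
    balanced_accuracy(as.character(y), preds)
  }
  keep <- integer(0)
  best <- -Inf
  for (s in seq_len(max_steps)) {
    cands <- setdiff(seq_len(p), keep)
    sc <- vapply(cands, function(j) score_set(c(keep, j)), 0)
    if (max(sc) <= best) break
    best <- max(sc)
    keep <- c(keep, cands[which.max(sc)])
  }
  if (length(keep) == 0) keep <- 1L
  keep
}

# Recursive feature elimination for the linear SVM: drops the feature with
# the smallest |weight|, one per round, down to `target` features.
rfe_select <- function(Xs, y, C, target) {
  keep <- seq_len(ncol(Xs))
  while (length(keep) > target) {
    fit <- e1071::svm(Xs[, keep, drop = FALSE], y, kernel = "linear",
                      cost = C, scale = FALSE, type = "C-classification")
    w <- crossprod(fit$coefs, fit$SV)
    drop_i <- which.min(abs(w))
    keep <- keep[-drop_i]
  }
  keep
}

# stratified (or plain) fold assignment; classes are distributed so that
# per-fold proportions deviate by at most one subject
make_folds <- function(y, k, stratified = TRUE) {
  n <- length(y)
  folds <- integer(n)
  if (stratified && (is.factor(y) || is.character(y))) {
    for (cl in unique(as.character(y))) {
      idx <- which(as.character(y) == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(sample.int(k), length(idx))
    }
  } else {
    folds <- rep_len(sample.int(k), n)[sample.int(n)]
  }
  folds
}

#' Repeated stratified two-layer cross-validation
#'
#' Outer folds estimate generalization on unseen subjects; inner folds tune
#' (mRMR k x model hyperparameters) by grid search, with standardization
#' and all feature selection fitted inside each inner-training partition
#' only. The best combination (ties broken toward fewer features, then
#' stronger regularization) is refit on the full outer-training set and
#' evaluated once on the outer test fold. With 10 repetitions of 10-fold
#' outer CV this yields 100 final models.
#'
#' @param ft a [feature_table()] (or plain numeric matrix)
#' @param target `"group"`, `"aq"`, `"spq_vis"`, `"spq_aud"`, or a vector
#'   of targets (factor/character = classification, numeric = regression)
#' @param models character vector of pipeline names: classifiers
#'   `"logistic_l1"`, `"logistic_l2"`, `"svm"`, `"rf"`; regressors
#'   `"linear_l1"`, `"linear_l2"`
#' @param grid a [model_grid()]
#' @param repeats,outer_k,inner_k cross-validation structure (default
#'   10 x 10 x 10)
#' @param seed RNG seed controlling every split
#' @param feature_types optional per-column type labels for per-type mRMR;
#'   derived from the feature table by default; `NULL` disables per-type
#'   selection
#' @param sfs_max_steps forward-selection cap for `logistic_l2`
#' @return object of class `cv_report`: `folds` data.frame (one row per
#'   outer fold x model: rep, fold, model, train/val/test scores, chosen
#'   hyperparameters, number of selected features), `summary` per model
#'   (mean and 95% CI of each score, baseline p), `task`
#' @export
run_two_layer_cv <- function(ft, target = "group",
                             models = c("logistic_l1"),
                             grid = model_grid(),
                             repeats = 10, outer_k = 10, inner_k = 10,
                             seed = 1, feature_types, sfs_max_steps = 20) {
  if (inherits(ft, "feature_table")) {
    X <- ft$values
    if (missing(feature_types)) feature_types <- feature_type(ft)
    y <- if (is.character(target) && length(target) == 1) {
      ft$subjects[[if (target == "group") "group" else target]]
    } else target
  } else {
    X <- as.matrix(ft)
    if (missing(feature_types)) feature_types <- NULL
    y <- target
  }
  classification <- is.factor(y) || is.character(y)
  if (classification) {
    y <- factor(as.character(y))
    if (nlevels(y) != 2) stop("classification targets need 2 classes")
    if (min(table(y)) < outer_k) {
      stop("need at least outer_k subjects per class for stratification")
    }
  } else {
    y <- as.numeric(y)
  }
  bad_cls <- c("logistic_l1", "logistic_l2", "svm", "rf")
  if (classification && any(models %in% c("linear_l1", "linear_l2"))) {
    stop("linear regressors require a numeric target")
  }
  if (!classification && any(models %in% bad_cls)) {
    stop("classifiers require a class target")
  }
  set.seed(seed)
  rows <- list()
  for (rep_i in seq_len(repeats)) {
    outer_folds <- make_folds(y, outer_k, stratified = classification)
    for (of in seq_len(outer_k)) {
      te <- outer_folds == of
      tr <- !te
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      inner_folds <- make_folds(ytr, inner_k, stratified = classification)
      for (model in models) {
        combos <- model_combos(model, grid)
        kgrid <- grid$mrmr_k
        val_acc <- matrix(0, length(kgrid), nrow(combos))
        for (inf in seq_len(inner_k)) {
          itr <- inner_folds != inf
          sc <- scaler_fit(Xtr[itr, , drop = FALSE])
          # one greedy pass at the largest k: prefixes give the smaller ks
          sel_full <- mrmr_select(scaler_apply(sc, Xtr[itr, , drop = FALSE]),
                                  ytr[itr], max(kgrid), feature_types)
          for (ki in seq_along(kgrid)) {
            pool <- prefix_pool(sel_full, feature_types, kgrid[ki])
            for (ci in seq_len(nrow(combos))) {
              fitobj <- fit_pipeline(model, Xtr[itr, , drop = FALSE],
                                     ytr[itr], pool,
                                     as.list(combos[ci, , drop = FALSE]),
                                     classification, sfs_max_steps)
              pr <- predict_pipeline(fitobj, Xtr[!itr, , drop = FALSE])
              s <- if (classification) {
                balanced_accuracy(ytr[!itr], pr)
              } else {
                -nmae(ytr[!itr], pr, mean(ytr[itr]))
              }
              val_acc[ki, ci] <- val_acc[ki, ci] + s / inner_k
            }
          }
        }
        # best combo; parsimony tie-break: smaller k, then stronger reg
        best <- which(val_acc >= max(val_acc) - 1e-12, arr.ind = TRUE)
        ord <- order(kgrid[best[, 1]], combos$reg_rank[best[, 2]])
        bk <- best[ord[1], 1]; bc <- best[ord[1], 2]
        sel_full <- mrmr_select(scaler_apply(scaler_fit(Xtr), Xtr), ytr,
                                max(kgrid), feature_types)
        pool <- prefix_pool(sel_full, feature_types, kgrid[bk])
        fitobj <- fit_pipeline(model, Xtr, ytr, pool,
                               as.list(combos[bc, , drop = FALSE]),
                               classification, sfs_max_steps)
        pr_te <- predict_pipeline(fitobj, X[te, , drop = FALSE])
        pr_tr <- predict_pipeline(fitobj, Xtr)
        if (classification) {
          test_s <- balanced_accuracy(y[te], pr_te)
          train_s <- balanced_accuracy(ytr, pr_tr)
        } else {
          test_s <- nmae(y[te], pr_te, mean(ytr))
          train_s <- nmae(ytr, pr_tr, mean(ytr))
        }
        val_s <- if (classification) val_acc[bk, bc] else -val_acc[bk, bc]
        hy <- combos[bc, setdiff(names(combos), "reg_rank"), drop = FALSE]
        rows[[length(rows) + 1]] <- data.frame(
          rep = rep_i, fold = of, model = model,
          train = train_s, validation = val_s, test = test_s,
          mrmr_k = kgrid[bk],
          hyper = paste(names(hy), signif(unlist(hy), 4), sep = "=",
                        collapse = ","),
          n_features = length(fitobj$keep),
          selected = paste(colnames(X)[fitobj$pool[fitobj$keep]],
                           collapse = ";"),
          test_idx = paste(which(te), collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  folds <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(unique(folds$model), function(m) {
    fm <- folds[folds$model == m, ]
    ci <- function(v) {
      se <- stats::sd(v) / sqrt(length(v))
      c(mean(v), mean(v) - 1.96 * se, mean(v) + 1.96 * se)
    }
    tv <- ci(fm$test); vv <- ci(fm$validation)
    p_base <- if (nrow(fm) < 6) NA_real_ else if (classification) {
      baseline_test(fm$test, 0.5, "greater")
    } else {
      baseline_test(fm$test, 1.0, "less")
    }
    data.frame(model = m, n_folds = nrow(fm),
               test_mean = tv[1], test_lo = tv[2], test_hi = tv[3],
               val_mean = vv[1], val_lo = vv[2], val_hi = vv[3],
               train_mean = mean(fm$train), p_baseline = p_base,
               stringsAsFactors = FALSE)
  }))
  structure(list(folds = folds, summary = summary,
                 task = if (classification) "classification" else
                   "regression",
                 repeats = repeats, outer_k = outer_k, inner_k = inner_k,
                 seed = seed),
            class = "cv_report")
}

# union of per-type selection prefixes at a smaller k (greedy selections
# are nested, so the first k picks of each type are the k-selection)
prefix_pool <- function(sel_full, type_labels, k) {
  if (is.null(type_labels)) return(sel_full[seq_len(min(k, length(sel_full)))])
  out <- integer(0)
  for (ty in unique(type_labels[sel_full])) {
    s <- sel_full[type_labels[sel_full] == ty]
    out <- c(out, s[seq_len(min(k, length(s)))])
  }
  out
}

#' @export
print.cv_report <- function(x, ...) {
  metric <- if (x$task == "classification") "balanced accuracy" else "nMAE"
  cat(sprintf("<cv_report> %s, %d repeats x %d outer folds (%d models/row)\n",
              x$task, x$repeats, x$outer_k, nrow(x$summary)))
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %-12s test %s %.3f [%.3f, %.3f], validation %.3f, p(baseline) %.3g\n",
                s$model, metric, s$test_mean, s$test_lo, s$test_hi,
                s$val_mean, s$p_baseline))
  }
  invisible(x)
}
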