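# Univariate group comparisons: permutation test on group means, Levene's
# test on variances, Benjamini-Hochberg FDR within feature types.

#' Permutation test for a difference in group means
#'
#' Statistic: absolute difference of group means. Group labels are permuted
#' `n_perm` times; when the total number of distinct assignments is at most
#' `n_perm` the null distribution is enumerated exhaustively (the p-value is
#' then the exact fraction of assignments reaching the observed statistic,
#' which includes the observed assignment itself); otherwise Monte-Carlo
#' sampling with the add-one correction `p = (b + 1)/(n_perm + 1)`.
#'
#' @param x,y numeric vectors for the two groups (each length >= 2)
#' @param n_perm number of permutations (default 10000)
#' @param seed optional seed for the Monte-Carlo path
#' @param exhaustive force (`TRUE`) or forbid (`FALSE`) exhaustive
#'   enumeration; by default enumeration is used whenever the number of
#'   distinct assignments is at most `n_perm`
#' @return list with `p`, `statistic`, `exhaustive`
#' @export
permutation_mean_test <- function(x, y, n_perm = 10000, seed = NULL,
                                  exhaustive = NULL) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  nx <- length(x); ny <- length(y)
  pool <- c(x, y)
  obs <- abs(mean(x) - mean(y))
  n_arrange <- choose(nx + ny, nx)
  tot <- sum(pool)
  stat_from_sum <- function(sx) abs(sx / nx - (tot - sx) / ny)
  if (exhaustive %||% (n_arrange <= n_perm)) {
    if (isTRUE(exhaustive) && n_arrange > 1e6) stop("too many arrangements")
    sums <- utils::combn(pool, nx, sum)
    stats_null <- stat_from_sum(sums)
    p <- mean(stats_null >= obs - 1e-12)
    return(list(p = p, statistic = obs, exhaustive = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  b <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(nx + ny, nx)
    if (stat_from_sum(sum(pool[idx])) >= obs - 1e-12) b <- b + 1L
  }
  list(p = (b + 1) / (n_perm + 1), statistic = obs, exhaustive = FALSE)
}

#' Levene's test for equality of variances (two groups)
#'
#' Classic Levene W on absolute deviations from the group centre (mean by
#' default; median gives the Brown-Forsythe variant), referred to the
#' F(k-1, N-k) distribution.
#'
#' @param x,y numeric vectors (each length >= 2)
#' @param center `"mean"` (classic) or `"median"` (Brown-Forsythe)
#' @return list with `W`, `p`, `df`
#' @export
levene_test <- function(x, y, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  cf <- if (center == "mean") mean else stats::median
  zx <- abs(x - cf(x))
  zy <- abs(y - cf(y))
  k <- 2
  N <- length(zx) + length(zy)
  zbar <- mean(c(zx, zy))
  num <- (N - k) * (length(zx) * (mean(zx) - zbar)^2 +
                    length(zy) * (mean(zy) - zbar)^2)
  den <- (k - 1) * (sum((zx - mean(zx))^2) + sum((zy - mean(zy))^2))
  if (den == 0) {
    if (num == 0) return(list(W = 0, p = 1, df = c(k - 1, N - k)))
    stop("degenerate within-group deviations")
  }
  W <- num / den
  list(W = W, p = stats::pf(W, k - 1, N - k, lower.tail = FALSE),
       df = c(k - 1, N - k))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone, capped at 1).
#' @param pvals numeric vector of raw p-values in `[0, 1]`
#' @return adjusted p-values
#' @export
fdr_bh <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Group statistics over a whole feature table
#'
#' For every feature: a permutation test on the group-mean difference (all
#' features share one set of label permutations, which is what makes the
#' table-level test fast) and Levene's test on variances; BH-FDR within
#' each feature type; significance at `alpha` on adjusted p.
#'
#' @param ft a [feature_table()]
#' @param group group labels (defaults to `ft$subjects$group`)
#' @param n_perm permutations (default 10000)
#' @param seed RNG seed for the permutations
#' @param alpha significance level (default 0.05)
#' @return object of class `group_stats`: `per_feature` data.frame
#'   (mean_diff, p_perm, levene_W, p_levene, p_perm_adj, p_levene_adj,
#'   type), `per_type` summary counts, `n_significant_types`
#' @export
group_stats <- function(ft, group = ft$subjects$group, n_perm = 10000,
                        seed = 1, alpha = 0.05) {
  X <- ft$values
  g <- group == group[1]
  n1 <- sum(g); n2 <- sum(!g)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 subjects")
  obs <- abs(colMeans(X[g, , drop = FALSE]) - colMeans(X[!g, , drop = FALSE]))
  tot <- colSums(X)
  set.seed(seed)
  # permuted |mean difference| for all features at once via an indicator
  # matrix product: n_perm x subjects times subjects x features
  Ind <- matrix(0, n_perm, nrow(X))
  for (i in seq_len(n_perm)) Ind[i, sample.int(nrow(X), n1)] <- 1
  S1 <- Ind %*% X                           # per-perm group-1 sums
  stat_null <- abs(S1 / n1 - sweep(-S1, 2, tot, `+`) / n2)
  b <- colSums(stat_null >= rep(obs, each = n_perm) - 1e-12)
  p_perm <- (b + 1) / (n_perm + 1)
  # vectorized classic Levene
  Z1 <- abs(sweep(X[g, , drop = FALSE], 2, colMeans(X[g, , drop = FALSE])))
  Z2 <- abs(sweep(X[!g, , drop = FALSE], 2, colMeans(X[!g, , drop = FALSE])))
  m1 <- colMeans(Z1); m2 <- colMeans(Z2)
  zbar <- (n1 * m1 + n2 * m2) / (n1 + n2)
  num <- (n1 + n2 - 2) * (n1 * (m1 - zbar)^2 + n2 * (m2 - zbar)^2)
  den <- colSums(sweep(Z1, 2, m1)^2) + colSums(sweep(Z2, 2, m2)^2)
  W <- ifelse(den > 0, num / den, 0)
  p_lev <- stats::pf(W, 1, n1 + n2 - 2, lower.tail = FALSE)
  type <- feature_type(ft)
  p_perm_adj <- p_lev_adj <- rep(NA_real_, ncol(X))
  for (ty in unique(type)) {
    idx <- type == ty
    p_perm_adj[idx] <- fdr_bh(p_perm[idx])
    p_lev_adj[idx] <- fdr_bh(p_lev[idx])
  }
  per_type <- do.call(rbind, lapply(unique(type), function(ty) {
    idx <- type == ty
    data.frame(type = ty, n = sum(idx),
               n_sig_mean = sum(p_perm_adj[idx] < alpha),
               n_sig_var = sum(p_lev_adj[idx] < alpha),
               pct_sig_mean = 100 * mean(p_perm_adj[idx] < alpha),
               pct_sig_var = 100 * mean(p_lev_adj[idx] < alpha),
               stringsAsFactors = FALSE)
  }))
  # a type is called significant when its FDR-significant share exceeds the
  # 5% chance level (the convention used for the age screen as well)
  per_type$flagged_mean <- per_type$pct_sig_mean > 100 * alpha
  per_type$flagged_var <- per_type$pct_sig_var > 100 * alpha
  structure(list(
    per_feature = data.frame(
      mean_diff = obs, p_perm = p_perm, levene_W = W, p_levene = p_lev,
      p_perm_adj = p_perm_adj, p_levene_adj = p_lev_adj, type = type,
      row.names = colnames(X)),
    per_type = per_type,
    n_significant_types = sum(per_type$flagged_mean | per_type$flagged_var),
    n_significant_types_mean = sum(per_type$flagged_mean),
    alpha = alpha), class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat("<group_stats> significant features (adjusted p <", x$alpha, "):\n")
  for (i in seq_len(nrow(x$per_type))) {
    cat(sprintf("  %-10s mean: %d/%d  variance: %d/%d\n",
                x$per_type$type[i], x$per_type$n_sig_mean[i],
                x$per_type$n[i], x$per_type$n_sig_var[i], x$per_type$n[i]))
  }
  invisible(x)
}
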