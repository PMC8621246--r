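#' Two-sample t-test for a single feature
#'
#' Classical two-sample t statistic with two-sided p-value. The default is the
#' pooled-variance (Student) flavour; Welch's unequal-variance form is
#' available behind `welch = TRUE`. Two guards handle constant microarray
#' probes: if both groups are constant and equal the test returns `t = 0`,
#' `p = 1`; if the pooled standard deviation is zero but the means differ it
#' returns an infinite `t` (signed by the mean difference) with `p = 0`.
#'
#' @param x_pos,x_neg Numeric vectors with at least two values each.
#' @param welch Use Welch's t-test instead of the pooled-variance form.
#' @return Named numeric vector `c(t = ..., p = ...)`.
#' @export
two_sample_ttest <- function(x_pos, x_neg, welch = FALSE) {
  if (length(x_pos) < 2 || length(x_neg) < 2) {
    zs_stop("each group needs at least 2 values", "zooselect_error_group_too_small")
  }
  res <- ttest_cols(matrix(x_pos, ncol = 1), matrix(x_neg, ncol = 1), welch = welch)
  c(t = res$t, p = res$p)
}

# Vectorised column-wise two-sample t-test shared by two_sample_ttest() and
# rank_features(); xp/xn are group sub-matrices with features in columns.
ttest_cols <- function(xp, xn, welch = FALSE) {
  n1 <- nrow(xp)
  n2 <- nrow(xn)
  m1 <- colMeans(xp)
  m2 <- colMeans(xn)
  v1 <- colSums(xp * xp) / n1 - m1 * m1
  v2 <- colSums(xn * xn) / n2 - m2 * m2
  v1 <- pmax(v1 * n1 / (n1 - 1), 0)  # unbiased, clamped against fp negatives
  v2 <- pmax(v2 * n2 / (n2 - 1), 0)
  diff <- m1 - m2
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(se2))
  }
  t <- diff / sqrt(se2)
  zero_se <- se2 == 0
  t[zero_se & diff == 0] <- 0
  t[zero_se & diff != 0] <- sign(diff[zero_se & diff != 0]) * Inf
  p <- 2 * stats::pt(-abs(t), df)
  p[zero_se & diff == 0] <- 1
  p[zero_se & diff != 0] <- 0
  list(t = unname(t), p = unname(p), df = unname(df))
}

#' Rank features by t-test association with the class label
#'
#' Computes one two-sample t-test per feature and orders features by ascending
#' p-value. Ties are broken by larger `|t|`, then by original feature index,
#' keeping the order deterministic.
#'
#' @param ds An [omics_dataset()] with >= 2 samples per class.
#' @param welch Use Welch's t-test (default: pooled-variance Student).
#' @return Object of class `FeatureRanking`: list with `order` (feature
#'   indices, best first), `t_stats`, `p_values`, `feature_ids`.
#' @export
rank_features <- function(ds, welch = FALSE) {
  pos <- ds$labels == "POS"
  if (sum(pos) < 2 || sum(!pos) < 2) {
    zs_stop("each class needs at least 2 samples", "zooselect_error_group_too_small")
  }
  res <- ttest_cols(ds$values[pos, , drop = FALSE],
                    ds$values[!pos, , drop = FALSE], welch = welch)
  ord <- order(res$p, -abs(res$t), seq_along(res$p))
  structure(list(order = ord, t_stats = res$t, p_values = res$p,
                 feature_ids = ds$feature_ids),
            class = "FeatureRanking")
}

#' @export
print.FeatureRanking <- function(x, ...) {
  cat(sprintf("<FeatureRanking> %d features; best: %s (p = %.3g)\n",
              length(x$order), x$feature_ids[x$order[1]], x$p_values[x$order[1]]))
  invisible(x)
}

#' Keep the top-k ranked features
#'
#' @param ds The dataset the ranking was computed on.
#' @param ranking A [rank_features()] result for `ds`.
#' @param k Number of features to keep (default 1000); capped at the feature
#'   count. Features are returned in ranking order.
#' @return An `OmicsDataset` restricted to the top-ranked features.
#' @export
top_k_subset <- function(ds, ranking, k = 1000) {
  stopifnot(inherits(ranking, "FeatureRanking"))
  if (length(ranking$order) != n_features(ds)) {
    zs_stop("ranking does not match dataset", "zooselect_error_dimension_mismatch")
  }
  if (k < 1) zs_stop("k must be >= 1", "zooselect_error_invalid_spec")
  subset_features(ds, ranking$order[seq_len(min(k, n_features(ds)))])
}

#' Ranking as an exportable table
#'
#' @param ranking A [rank_features()] result.
#' @return `data.frame` with columns `feature_id`, `t`, `p`, `rank`.
#' @export
ranking_table <- function(ranking) {
  rk <- integer(length(ranking$order))
  rk[ranking$order] <- seq_along(ranking$order)
  data.frame(feature_id = ranking$feature_ids,
             t = ranking$t_stats,
             p = ranking$p_values,
             rank = rk)
}
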