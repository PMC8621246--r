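#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `Acc = (TP+TN)/(TP+FN+TN+FP)`, where
#' TP/FN count correctly/incorrectly predicted positive samples and TN/FP the
#' true negatives and false positives.
#'
#' @param tp,fn,tn,fp Non-negative integer confusion counts.
#' @return Named numeric vector `c(Sn, Sp, Acc)`.
#' @export
metrics <- function(tp, fn, tn, fp) {
  counts <- c(tp, fn, tn, fp)
  if (any(counts < 0) || any(counts != round(counts))) {
    zs_stop("confusion counts must be non-negative integers",
            "zooselect_error_invalid_spec")
  }
  P <- tp + fn
  N <- tn + fp
  if (P == 0) zs_stop("Sn undefined: no positive samples", "zooselect_error_undefined_metric")
  if (N == 0) zs_stop("Sp undefined: no negative samples", "zooselect_error_undefined_metric")
  c(Sn = tp / P, Sp = tn / N, Acc = (tp + tn) / (P + N))
}

confusion_counts <- function(truth, pred) {
  pos <- truth == "POS"
  c(tp = sum(pos & pred == "POS"), fn = sum(pos & pred == "NEG"),
    tn = sum(!pos & pred == "NEG"), fp = sum(!pos & pred == "POS"))
}

#' Stratified k-fold cross-validated accuracy of a feature subset
#'
#' Each sample is predicted exactly once across the folds; the accuracy is
#' pooled (total correct over total samples), which coincides with the mean of
#' per-fold accuracies when folds are equally sized. Default is the
#' three-fold protocol with seed 0.
#'
#' @param ds An [omics_dataset()] with >= k samples per class.
#' @param subset Integer feature indices to use.
#' @param classifier Classifier id, see [predict_labels()].
#' @param seed Fold-assignment seed (default 0).
#' @param k Number of folds (default 3).
#' @param folds Optional precomputed folds from [stratified_kfold_indices()],
#'   so competing subsets can be scored on identical folds.
#' @return Pooled accuracy in `[0, 1]`.
#' @export
s3fcv_accuracy <- function(ds, subset, classifier = "SVM", seed = 0, k = 3,
                           folds = NULL) {
  folds <- folds %||% stratified_kfold_indices(ds$labels, k, seed)
  correct <- 0L
  for (f in folds) {
    pred <- predict_labels(classifier,
                           ds$values[f$train, subset, drop = FALSE],
                           ds$labels[f$train],
                           ds$values[f$test, subset, drop = FALSE])
    correct <- correct + sum(pred == ds$labels[f$test])
  }
  correct / n_samples(ds)
}

#' Maximum accuracy over the five-classifier panel
#'
#' Scores the subset with each of LR, KNN, NBayes, DT and SVM under the same
#' cross-validation folds and reports the best (mAcc).
#'
#' @inheritParams s3fcv_accuracy
#' @return List with `mAcc` and the named per-classifier `accuracies`.
#' @export
max_accuracy <- function(ds, subset, seed = 0, k = 3) {
  folds <- stratified_kfold_indices(ds$labels, k, seed)
  panel <- c("LR", "KNN", "NBAYES", "DT", "SVM")
  accs <- vapply(panel, function(cl) s3fcv_accuracy(ds, subset, cl, folds = folds),
                 numeric(1))
  list(mAcc = max(accs), accuracies = accs)
}

#' Incremental feature selection curve along a ranking
#'
#' Entry `k` of the curve is the cross-validated accuracy of the top-`k`
#' ranked features, tracing how performance grows (or saturates) as features
#' are added in ranking order.
#'
#' @param ds An [omics_dataset()].
#' @param ranking A [rank_features()] result for `ds`.
#' @param max_k Curve length (default 100, capped at the feature count).
#' @param classifier Classifier id (default `"SVM"`).
#' @param seed Fold seed.
#' @return `data.frame` with columns `k` and `accuracy`.
#' @export
ifs_curve <- function(ds, ranking, max_k = 100, classifier = "SVM", seed = 0) {
  stopifnot(inherits(ranking, "FeatureRanking"))
  max_k <- min(max_k, n_features(ds))
  folds <- stratified_kfold_indices(ds$labels, 3, seed)
  acc <- vapply(seq_len(max_k), function(k) {
    s3fcv_accuracy(ds, ranking$order[seq_len(k)], classifier, folds = folds)
  }, numeric(1))
  data.frame(k = seq_len(max_k), accuracy = acc)
}
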