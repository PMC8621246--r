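#' Configure dynamic recursive feature elimination
#'
#' dRFE removes a variable number (1 to `max_step`) of least-important
#' features per iteration, where importance is the absolute coefficient of a
#' linear SVM refit on the current subset, and every candidate removal is
#' scored by stratified three-fold cross-validated SVM accuracy on fixed
#' folds.
#'
#' @param max_step Maximum features removed per iteration (default 7).
#' @param cv_seed Seed fixing the evaluation folds for the whole refinement,
#'   so candidate comparisons are paired.
#' @param eval_classifier Classifier used for candidate scoring (default
#'   `"SVM"`).
#' @return A list of class `DrfeConfig`.
#' @export
drfe_config <- function(max_step = 7, cv_seed = 0, eval_classifier = "SVM") {
  if (max_step < 1) zs_stop("max_step must be >= 1", "zooselect_error_invalid_spec")
  structure(list(max_step = as.integer(max_step), cv_seed = as.integer(cv_seed),
                 eval_classifier = match.arg(toupper(eval_classifier), CLASSIFIER_IDS)),
            class = "DrfeConfig")
}

#' Rank a feature subset by linear-SVM weight magnitude
#'
#' Fits a linear SVM on the training data restricted to `subset` and returns
#' the subset ordered by increasing absolute weight (least important first).
#' Ties go to the smaller original feature index.
#'
#' @param train An [omics_dataset()].
#' @param subset Integer feature indices, at least 2.
#' @return `subset` reordered by ascending `|weight|`.
#' @export
rank_by_linear_svm <- function(train, subset) {
  if (length(subset) < 2) {
    zs_stop("subset must contain at least 2 features", "zooselect_error_invalid_spec")
  }
  x <- train$values[, subset, drop = FALSE]
  fit <- tryCatch(
    e1071::svm(x = x, y = train$labels, kernel = "linear", scale = FALSE),
    error = function(e) zs_stop(sprintf("degenerate linear SVM fit: %s",
                                        conditionMessage(e)),
                                "zooselect_error_degenerate_fit"))
  w <- drop(crossprod(fit$coefs, fit$SV))
  subset[order(abs(w), subset)]
}

#' Refine a feature subset by dynamic recursive feature elimination
#'
#' Starting from `start_subset`, repeatedly refits the linear-SVM ranking,
#' evaluates removal of the `k = 1..max_step` least-important features, moves
#' to the best-scoring candidate (ties prefer the larger removal, i.e. the
#' smaller subset) and records it, until one feature remains. The recorded
#' subset with maximal cross-validated accuracy is returned; because the
#' starting subset is itself recorded, the returned accuracy can never fall
#' below the starting accuracy on the same folds.
#'
#' @param train Training dataset.
#' @param start_subset Integer feature indices (>= 1).
#' @param cfg A [drfe_config()].
#' @return List of class `DrfeResult`: `subset` (best recorded), `accuracy`,
#'   `trace` (`data.frame` with `size`, `accuracy`, `removed` id-list column),
#'   `best_index` into the trace.
#' @export
drfe_refine <- function(train, start_subset, cfg = drfe_config()) {
  start_subset <- as.integer(start_subset)
  if (length(start_subset) < 1) {
    zs_stop("start_subset must contain at least 1 feature", "zooselect_error_invalid_spec")
  }
  folds <- stratified_kfold_indices(train$labels, 3, cfg$cv_seed)
  score <- function(sub) s3fcv_accuracy(train, sub, cfg$eval_classifier, folds = folds)

  cur <- start_subset
  subsets <- list(cur)
  sizes <- length(cur)
  accs <- score(cur)
  removed <- list(integer(0))

  while (length(cur) > 1) {
    ranked <- rank_by_linear_svm(train, cur)
    ks <- seq_len(min(cfg$max_step, length(cur) - 1))
    cand_acc <- vapply(ks, function(k) score(setdiff(cur, ranked[seq_len(k)])),
                       numeric(1))
    k <- max(ks[cand_acc == max(cand_acc)])  # ties -> larger removal
    rem <- ranked[seq_len(k)]
    cur <- setdiff(cur, rem)
    subsets <- c(subsets, list(cur))
    sizes <- c(sizes, length(cur))
    accs <- c(accs, cand_acc[k])
    removed <- c(removed, list(rem))
  }

  best_candidates <- which(accs == max(accs))
  # ties -> smallest subset (sizes strictly decrease along the trace)
  best <- best_candidates[which.min(sizes[best_candidates])]
  structure(list(subset = subsets[[best]],
                 accuracy = accs[best],
                 trace = data.frame(size = sizes, accuracy = accs,
                                    removed = I(removed)),
                 best_index = best),
            class = "DrfeResult")
}

#' @export
print.DrfeResult <- function(x, ...) {
  cat(sprintf("<DrfeResult> %d -> %d features, CV accuracy %.4f (%d recorded subsets)\n",
              x$trace$size[1], length(x$subset), x$accuracy, nrow(x$trace)))
  invisible(x)
}
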