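#' Configure the wrapper fitness function
#'
#' The fitness of a candidate feature mask combines the classification error
#' `E` of a classifier trained/evaluated on a stratified 2:1 split of the
#' training data with the selected-feature ratio:
#' `fitness = omega * E + (1 - omega) * Selected / Dimension`. Lower is
#' better. `omega = 0.9` weights error nine times as heavily as sparsity.
#'
#' @param omega Weight on the error term, in `[0, 1]` (default 0.9).
#' @param classifier Fitness classifier id (default `"NBAYES"`), see
#'   [predict_labels()].
#' @param seed Seed for the inner 2:1 split.
#' @return A list of class `FitnessConfig`.
#' @export
fitness_config <- function(omega = 0.9, classifier = "NBAYES", seed = 0) {
  if (omega < 0 || omega > 1) zs_stop("omega must lie in [0, 1]", "zooselect_error_invalid_spec")
  structure(list(omega = omega,
                 classifier = match.arg(toupper(classifier), CLASSIFIER_IDS),
                 seed = as.integer(seed)),
            class = "FitnessConfig")
}

#' Stratified 2:1 inner split of a training set
#'
#' Drawn once per optimizer run and reused for every fitness evaluation of
#' that run, so fitness values are comparable across agents and iterations.
#'
#' @param train_ds An [omics_dataset()] with >= 3 samples per class.
#' @param seed Integer seed.
#' @return List with `fit` and `eval` datasets (2/3 and 1/3 of each class).
#' @export
make_inner_split <- function(train_ds, seed = 0) {
  grp <- stratified_assignment(train_ds$labels, 3, seed, min_per_class = 3)
  list(fit = subset_samples(train_ds, which(grp != 3)),
       eval = subset_samples(train_ds, which(grp == 3)))
}

#' Classification error of a masked feature set
#'
#' Trains `classifier` on `fit_part` restricted to the selected features and
#' returns `1 - accuracy` on `eval_part`.
#'
#' @param fit_part,eval_part Datasets sharing the same feature space.
#' @param mask Binary (0/1 or logical) vector over features with >= 1 bit set.
#' @param classifier Classifier id, see [predict_labels()].
#' @return Error rate in `[0, 1]`.
#' @export
classification_error <- function(fit_part, eval_part, mask, classifier = "NBAYES") {
  sel <- which(mask > 0)
  if (length(sel) == 0) zs_stop("mask selects no features", "zooselect_error_empty_mask")
  pred <- predict_labels(classifier,
                         fit_part$values[, sel, drop = FALSE], fit_part$labels,
                         eval_part$values[, sel, drop = FALSE])
  mean(pred != eval_part$labels)
}

#' Fitness value from its components
#'
#' The exact arithmetic used by every optimizer:
#' `omega * error_rate + (1 - omega) * n_selected / dimension`.
#'
#' @param error_rate Classification error `E` in `[0, 1]`.
#' @param n_selected Number of selected features.
#' @param dimension Total number of features.
#' @param omega Error weight.
#' @return Scalar fitness (lower is better).
#' @export
fitness_value <- function(error_rate, n_selected, dimension, omega = 0.9) {
  omega * error_rate + (1 - omega) * n_selected / dimension
}

#' Evaluate the wrapper fitness of a feature mask
#'
#' @param mask Binary vector of length `n_features(train_ds)` with >= 1 bit set.
#' @param train_ds Training dataset.
#' @param cfg A [fitness_config()].
#' @return A list of class `FitnessValue` with `value`, `error_rate`,
#'   `n_selected`, `dimension`.
#' @export
fitness <- function(mask, train_ds, cfg = fitness_config()) {
  if (length(mask) != n_features(train_ds)) {
    zs_stop("mask length does not match the feature count",
            "zooselect_error_dimension_mismatch")
  }
  evaluator <- make_fitness_evaluator(train_ds, cfg)
  evaluator(mask)
}

#' @export
print.FitnessValue <- function(x, ...) {
  cat(sprintf("<FitnessValue> %.6f (E = %.4f, selected = %d/%d)\n",
              x$value, x$error_rate, x$n_selected, x$dimension))
  invisible(x)
}

# Build a closure evaluating masks against a fixed inner split. For the
# Gaussian NB fitness classifier the per-feature log-density margins on the
# eval part are precomputed once, reducing a single evaluation to one
# matrix-vector product and a whole-population evaluation (the "batch"
# attribute) to one matrix product; numerically identical to
# classification_error() with classifier = "NBAYES" up to summation order.
make_fitness_evaluator <- function(train_ds, cfg) {
  split <- make_inner_split(train_ds, cfg$seed)
  d <- n_features(train_ds)
  omega <- cfg$omega
  wrap <- function(e, ns) {
    structure(list(value = fitness_value(e, ns, d, omega),
                   error_rate = e, n_selected = ns, dimension = d),
              class = "FitnessValue")
  }
  if (cfg$classifier == "NBAYES") {
    fit <- nb_train(split$fit$values, split$fit$labels)
    margins <- nb_margin_matrix(fit, split$eval$values)
    prior <- fit$log_prior_diff
    truth_pos <- split$eval$labels == "POS"
    f <- function(mask) {
      ns <- sum(mask > 0)
      if (ns == 0) zs_stop("mask selects no features", "zooselect_error_empty_mask")
      score <- drop(margins %*% mask) + prior
      wrap(mean((score > 0) != truth_pos), ns)
    }
    attr(f, "batch") <- function(m) {
      ns <- rowSums(m > 0)
      if (any(ns == 0)) zs_stop("mask selects no features", "zooselect_error_empty_mask")
      scores <- margins %*% t(m) + prior
      e <- colMeans((scores > 0) != truth_pos)
      list(values = fitness_value(e, ns, d, omega), errors = e, n_selected = ns)
    }
    f
  } else {
    function(mask) {
      ns <- sum(mask > 0)
      if (ns == 0) zs_stop("mask selects no features", "zooselect_error_empty_mask")
      wrap(classification_error(split$fit, split$eval, mask, cfg$classifier), ns)
    }
  }
}
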