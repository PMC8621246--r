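#' Configure the ensemble feature-selection pipeline
#'
#' @param vote_threshold Minimum number of engines (out of nine) that must
#'   select a feature for it to enter the majority subset; the default 5
#'   encodes "more than four". If no feature reaches the threshold it is
#'   decremented until the subset is non-empty.
#' @param runs_per_engine Seeded restarts per engine (default 10); the run
#'   with the best validation accuracy wins.
#' @param iterations Optimizer iterations `T` per run (default 150).
#' @param prefilter_k Features kept by the t-test prefilter (default 1000).
#' @param fitness A [fitness_config()].
#' @param final_classifier Classifier for the final model (default `"KNN"`).
#' @param drfe_max_step Maximum features removed per dRFE iteration
#'   (default 7).
#' @param engine_N Optional named list overriding per-engine population sizes,
#'   e.g. `list(PSO = 20)`; engines default to their tuned sizes.
#' @return A list of class `ZooConfig`.
#' @export
zoo_config <- function(vote_threshold = 5, runs_per_engine = 10, iterations = 150,
                       prefilter_k = 1000, fitness = fitness_config(),
                       final_classifier = "KNN", drfe_max_step = 7,
                       engine_N = list()) {
  if (vote_threshold < 1 || vote_threshold > 9) {
    zs_stop("vote_threshold must lie in 1..9", "zooselect_error_invalid_spec")
  }
  if (runs_per_engine < 1) {
    zs_stop("runs_per_engine must be >= 1", "zooselect_error_invalid_spec")
  }
  structure(list(vote_threshold = as.integer(vote_threshold),
                 runs_per_engine = as.integer(runs_per_engine),
                 iterations = as.integer(iterations),
                 prefilter_k = as.integer(prefilter_k),
                 fitness = fitness,
                 final_classifier = match.arg(toupper(final_classifier), CLASSIFIER_IDS),
                 drfe_max_step = as.integer(drfe_max_step),
                 engine_N = engine_N),
            class = "ZooConfig")
}

#' The nine engine identifiers with their default population sizes
#'
#' @return `data.frame` with columns `algorithm` and `N`.
#' @export
zoo_engines <- function() {
  data.frame(algorithm = SI_ALGORITHMS,
             N = vapply(SI_ALGORITHMS, function(a) as.integer(si_defaults(a)$N), integer(1)),
             row.names = NULL)
}

#' Best mask over repeated seeded engine runs
#'
#' Executes `runs` seeded runs of one engine on the training set; each run's
#' best mask is scored by training the fitness classifier on the training set
#' (restricted to the mask) and measuring accuracy on the validation set. The
#' mask with the highest validation accuracy wins; ties prefer fewer selected
#' features, then the earlier run.
#'
#' @param engine Engine id, see [zoo_engines()].
#' @param train,validation Datasets over the same (prefiltered) feature space.
#' @param runs Number of seeded runs; run `r` uses seed `base_seed + r - 1`
#'   for both the optimizer and its inner fitness split.
#' @param fit_cfg A [fitness_config()].
#' @param iterations Optimizer iterations per run.
#' @param base_seed First run seed.
#' @param N Optional population-size override.
#' @return List with `mask` (0/1 vector), `validation_accuracy`, `run` index
#'   and per-run `history` of validation accuracies.
#' @export
best_of_runs <- function(engine, train, validation, runs, fit_cfg = fitness_config(),
                         iterations = 150, base_seed = 0, N = NULL) {
  best <- NULL
  val_accs <- numeric(runs)
  for (r in seq_len(runs)) {
    s <- base_seed + r - 1
    cfg <- swarm_config(engine, N = N, T = iterations, seed = s)
    fc <- fit_cfg
    fc$seed <- s
    res <- run_si(train, cfg, fc)
    sel <- which(res$best_mask == 1)
    pred <- predict_labels(fit_cfg$classifier,
                           train$values[, sel, drop = FALSE], train$labels,
                           validation$values[, sel, drop = FALSE])
    acc <- mean(pred == validation$labels)
    val_accs[r] <- acc
    if (is.null(best) || acc > best$validation_accuracy ||
        (acc == best$validation_accuracy && length(sel) < sum(best$mask))) {
      best <- list(mask = res$best_mask, validation_accuracy = acc, run = r)
    }
  }
  best$history <- val_accs
  best
}

#' Count per-feature votes across the nine engine masks
#'
#' @param masks A 9-row 0/1 matrix (or list of nine equal-length 0/1 vectors),
#'   one row per engine over the prefiltered features.
#' @return List of class `VoteTally` with `counts` (integer vector, 0..9) and
#'   the `contributing_masks` matrix.
#' @export
tally_votes <- function(masks) {
  if (is.list(masks)) {
    if (length(unique(lengths(masks))) != 1) {
      zs_stop("engine masks have differing lengths", "zooselect_error_dimension_mismatch")
    }
    masks <- do.call(rbind, masks)
  }
  structure(list(counts = as.integer(colSums(masks)),
                 contributing_masks = masks),
            class = "VoteTally")
}

#' Majority-vote feature subset
#'
#' Features selected by at least `threshold` engines. If no feature reaches
#' the threshold it is decremented by one until the subset is non-empty; if
#' no engine selected any feature at all, an error is raised.
#'
#' @param tally A [tally_votes()] result.
#' @param threshold Vote threshold (default 5, i.e. "more than four" of nine).
#' @return Sorted integer feature indices.
#' @export
majority_subset <- function(tally, threshold = 5) {
  stopifnot(inherits(tally, "VoteTally"))
  if (threshold < 1) zs_stop("threshold must be >= 1", "zooselect_error_invalid_spec")
  if (all(tally$counts == 0)) {
    zs_stop("no engine selected any feature", "zooselect_error_no_votes")
  }
  th <- threshold
  repeat {
    sel <- which(tally$counts >= th)
    if (length(sel) > 0) return(sel)
    th <- th - 1
  }
}

#' Run the full ensemble feature-selection pipeline
#'
#' Stages: (1) stratified 1:1:1 split into train/validation/test; (2) t-test
#' ranking on the training set and top-`prefilter_k` prefilter; (3) for each
#' of the nine engines, `runs_per_engine` seeded runs with validation-based
#' run selection; (4) majority vote over the nine winning masks; (5) dynamic
#' recursive feature elimination on the training set; (6) final model with
#' `final_classifier`, reporting validation and test accuracy. Deterministic
#' under the master seed, which derives the split seed, every engine-run seed
#' and the dRFE fold seed by fixed offsets.
#'
#' @param ds An [omics_dataset()] with >= 3 samples per class.
#' @param cfg A [zoo_config()].
#' @param seed Master seed.
#' @return Object of class `ZooResult`; see Details.
#' @details The result carries `feature_ids`/`feature_indices` (final subset,
#'   over the prefiltered training feature space), `votes` (per final
#'   feature), `feature_table` (per prefiltered feature: id, votes, in_final),
#'   `majority_indices`, `drfe` (the [drfe_refine()] result),
#'   `validation_accuracy`, `test_accuracy`, `validation_metrics`,
#'   `test_metrics` (Sn/Sp/Acc), `engine_masks`, `tally` and the resolved
#'   configuration.
#' @export
run_zoo <- function(ds, cfg = zoo_config(), seed = 0) {
  stopifnot(inherits(ds, "OmicsDataset"), inherits(cfg, "ZooConfig"))
  with_seed(seed, {
    split <- stratified_three_way_split(ds, seed)
    ranking <- rank_features(split$train)
    k <- min(cfg$prefilter_k, n_features(ds))
    keep <- ranking$order[seq_len(k)]
    train <- subset_features(split$train, keep)
    validation <- subset_features(split$validation, keep)
    test <- subset_features(split$test, keep)

    engines <- SI_ALGORITHMS
    masks <- matrix(0, length(engines), k)
    engine_val <- numeric(length(engines))
    for (e in seq_along(engines)) {
      bor <- best_of_runs(engines[e], train, validation,
                          runs = cfg$runs_per_engine, fit_cfg = cfg$fitness,
                          iterations = cfg$iterations,
                          base_seed = seed + 1000L * e,
                          N = cfg$engine_N[[engines[e]]])
      masks[e, ] <- bor$mask
      engine_val[e] <- bor$validation_accuracy
    }
    tally <- tally_votes(masks)
    majority <- majority_subset(tally, cfg$vote_threshold)

    dr <- drfe_refine(train, majority,
                      drfe_config(cfg$drfe_max_step, cv_seed = seed + 777L))
    final <- dr$subset

    eval_part <- function(part) {
      pred <- predict_labels(cfg$final_classifier,
                             train$values[, final, drop = FALSE], train$labels,
                             part$values[, final, drop = FALSE])
      cc <- confusion_counts(part$labels, pred)
      metrics(cc[["tp"]], cc[["fn"]], cc[["tn"]], cc[["fp"]])
    }
    val_m <- eval_part(validation)
    test_m <- eval_part(test)

    structure(list(feature_ids = train$feature_ids[final],
                   feature_indices = final,
                   votes = tally$counts[final],
                   feature_table = data.frame(
                     feature_id = train$feature_ids,
                     votes = tally$counts,
                     in_final = seq_len(k) %in% final),
                   majority_indices = majority,
                   drfe = dr,
                   validation_accuracy = unname(val_m["Acc"]),
                   test_accuracy = unname(test_m["Acc"]),
                   validation_metrics = val_m,
                   test_metrics = test_m,
                   engine_masks = stats::setNames(split(masks, seq_along(engines)), engines),
                   engine_validation_accuracy = stats::setNames(engine_val, engines),
                   prefiltered_ids = train$feature_ids,
                   split = split$assignment,
                   seed = seed,
                   config = cfg),
              class = "ZooResult")
  })
}

#' @export
print.ZooResult <- function(x, ...) {
  cat(sprintf("<ZooResult> %d features selected (majority %d -> dRFE %d)\n",
              length(x$feature_ids), length(x$majority_indices), length(x$feature_ids)))
  cat(sprintf("  validation Acc %.4f | test Acc %.4f (classifier %s)\n",
              x$validation_accuracy, x$test_accuracy, x$config$final_classifier))
  invisible(x)
}

#' Write pipeline results as TSV files
#'
#' Writes `selected_features.tsv` (feature_id, votes, in_final over all
#' prefiltered features) and `metrics.tsv` (Sn/Sp/Acc for the validation and
#' test parts) under `dir`.
#'
#' @param result A [run_zoo()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_zoo_results <- function(result, dir) {
  stopifnot(inherits(result, "ZooResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$feature_table,
                     file.path(dir, "selected_features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mt <- data.frame(part = c("validation", "test"),
                   rbind(result$validation_metrics, result$test_metrics))
  utils::write.table(mt, file.path(dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
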