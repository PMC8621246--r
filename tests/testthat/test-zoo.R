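test_that("vote tallies are per-feature column sums with length checking", {
  masks <- rbind(rep(1, 4), rep(1, 4), matrix(0, 7, 4))
  expect_equal(tally_votes(masks)$counts, rep(2L, 4))
  expect_equal(tally_votes(matrix(1, 9, 3))$counts, rep(9L, 3))
  lst <- replicate(9, c(1, 0, 1), simplify = FALSE)
  expect_equal(tally_votes(lst)$counts, c(9L, 0L, 9L))
  bad <- list(c(1, 0), c(1, 0, 1))
  expect_error(tally_votes(bad), class = "zooselect_error_dimension_mismatch")
})

test_that("majority subset applies the >= 5 rule with decrementing fallback", {
  t1 <- tally_votes(rbind(matrix(1, 9, 1), matrix(0, 0, 1)))
  counts_to_tally <- function(counts) {
    m <- matrix(0, 9, length(counts))
    for (j in seq_along(counts)) if (counts[j] > 0) m[seq_len(counts[j]), j] <- 1
    tally_votes(m)
  }
  expect_equal(majority_subset(counts_to_tally(c(9, 5, 4, 0))), c(1L, 2L))
  expect_equal(majority_subset(counts_to_tally(c(4, 3, 2, 1)), threshold = 5), 1L)
  expect_equal(majority_subset(counts_to_tally(rep(9, 6))), 1:6)
  expect_error(majority_subset(counts_to_tally(c(0, 0, 0))),
               class = "zooselect_error_no_votes")
})

test_that("best_of_runs returns the argmax over validation accuracy", {
  sim <- toy_dataset(n_pos = 15, n_neg = 15, d = 30, n_informative = 3, seed = 33)
  sp <- stratified_three_way_split(sim$dataset, seed = 0)
  out <- best_of_runs("GWO", sp$train, sp$validation, runs = 3,
                      fit_cfg = fitness_config(), iterations = 8, base_seed = 10)
  expect_length(out$history, 3)
  expect_equal(out$validation_accuracy, max(out$history))
  expect_gte(sum(out$mask), 1)
  # runs = 1 reduces to that run's best mask
  one <- best_of_runs("GWO", sp$train, sp$validation, runs = 1,
                      fit_cfg = fitness_config(), iterations = 8, base_seed = 10)
  ref <- run_si(sp$train, swarm_config("GWO", T = 8, seed = 10),
                fitness_config(seed = 10))
  expect_identical(one$mask, ref$best_mask)
})

test_that("the pipeline wires the stages together and respects containment", {
  sim <- toy_dataset(n_pos = 24, n_neg = 24, d = 120, n_informative = 5,
                     effect = 3, seed = 34)
  cfg <- zoo_config(iterations = 8, runs_per_engine = 1, prefilter_k = 40)
  res <- run_zoo(sim$dataset, cfg, seed = 2)
  k <- 40
  expect_equal(nrow(res$feature_table), k)
  # dRFE subset within the majority subset within the union of engine masks
  union_sel <- which(Reduce(`+`, res$engine_masks) > 0)
  expect_true(all(res$majority_indices %in% union_sel))
  expect_true(all(res$feature_indices %in% res$majority_indices))
  expect_true(all(res$votes >= 1))
  expect_true(res$validation_accuracy >= 0 && res$validation_accuracy <= 1)
  expect_true(res$test_accuracy >= 0 && res$test_accuracy <= 1)
  # dRFE cannot lose CV accuracy relative to the majority subset
  expect_gte(res$drfe$accuracy, res$drfe$trace$accuracy[1])
  # the planted signal at effect 3 should dominate the final subset
  planted_ids <- sim$dataset$feature_ids[sim$planted]
  expect_gte(sum(res$feature_ids %in% planted_ids), 1)
})

test_that("the pipeline is deterministic and rejects undersized classes", {
  sim <- toy_dataset(n_pos = 12, n_neg = 12, d = 60, n_informative = 3, seed = 35)
  cfg <- zoo_config(iterations = 3, runs_per_engine = 1, prefilter_k = 25)
  r1 <- run_zoo(sim$dataset, cfg, seed = 5)
  r2 <- run_zoo(sim$dataset, cfg, seed = 5)
  expect_identical(r1$feature_ids, r2$feature_ids)
  expect_identical(r1$feature_table, r2$feature_table)
  expect_identical(r1$test_accuracy, r2$test_accuracy)

  tiny <- toy_dataset(n_pos = 2, n_neg = 12, d = 20, seed = 36)
  expect_error(run_zoo(tiny$dataset, cfg, seed = 1),
               class = "zooselect_error_class_too_small")
})

test_that("results are written as stable TSV files", {
  sim <- toy_dataset(n_pos = 12, n_neg = 12, d = 60, n_informative = 3, seed = 35)
  cfg <- zoo_config(iterations = 3, runs_per_engine = 1, prefilter_k = 25)
  res <- run_zoo(sim$dataset, cfg, seed = 5)
  dir <- tempfile()
  write_zoo_results(res, dir)
  feat <- read.delim(file.path(dir, "selected_features.tsv"))
  expect_equal(nrow(feat), 25)
  expect_named(feat, c("feature_id", "votes", "in_final"))
  met <- read.delim(file.path(dir, "metrics.tsv"))
  expect_equal(met$part, c("validation", "test"))
  expect_true(all(c("Sn", "Sp", "Acc") %in% names(met)))
})

test_that("engine listing exposes the nine tuned defaults", {
  eng <- zoo_engines()
  expect_equal(nrow(eng), 9)
  expect_setequal(eng$algorithm,
                  c("GWO", "WOA", "BA", "CS", "FA", "MFO", "PSO", "MRFO", "DF"))
  expect_equal(eng$N[eng$algorithm == "MFO"], 90L)
  expect_equal(eng$N[eng$algorithm == "PSO"], 80L)
})
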