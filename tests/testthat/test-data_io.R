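test_that("loading a delimited matrix round-trips shapes, values and labels", {
  sim <- toy_dataset(n_pos = 3, n_neg = 3, d = 4, seed = 7)
  files <- write_temp_csv(sim$dataset)
  ds <- load_dataset(files$matrix, files$labels, orientation = "samples")
  expect_equal(n_samples(ds), 6)
  expect_equal(n_features(ds), 4)
  expect_equal(ds$labels, sim$dataset$labels)
  # values survive the text round-trip to printed precision
  expect_equal(ds$values, sim$dataset$values, tolerance = 1e-6)
  # loading twice gives bitwise-identical datasets
  expect_identical(ds, load_dataset(files$matrix, files$labels, orientation = "samples"))
})

test_that("features-in-rows orientation and label vectors are supported", {
  sim <- toy_dataset(n_pos = 4, n_neg = 4, d = 5, seed = 8)
  path <- tempfile(fileext = ".tsv")
  write_dataset_tsv(sim$dataset, path)
  ds <- load_dataset(path, as.character(sim$dataset$labels), orientation = "features")
  expect_equal(dim(ds$values), dim(sim$dataset$values))
  expect_equal(ds$values, sim$dataset$values, tolerance = 1e-6)
})

test_that("loader and constructor reject bad inputs with named conditions", {
  expect_error(load_dataset(tempfile(), c("A", "B")),
               class = "zooselect_error_unreadable_file")
  sim <- toy_dataset(n_pos = 3, n_neg = 3, d = 4, seed = 7)
  files <- write_temp_csv(sim$dataset)
  expect_error(load_dataset(files$matrix, rep(c("A", "B", "C"), 2),
                            orientation = "samples"),
               class = "zooselect_error_labels_not_binary")
  expect_error(load_dataset(files$matrix, c("A", "B"), orientation = "samples"),
               class = "zooselect_error_dimension_mismatch")
})

test_that("positive class defaults to the lexicographically larger label", {
  m <- matrix(rnorm(12), 6, 2)
  ds <- omics_dataset(m, c("tumor", "ctrl", "tumor", "ctrl", "tumor", "ctrl"))
  expect_equal(as.character(ds$labels),
               c("POS", "NEG", "POS", "NEG", "POS", "NEG"))
  ds2 <- omics_dataset(m, c("tumor", "ctrl", "tumor", "ctrl", "tumor", "ctrl"),
                       positive_label = "ctrl")
  expect_equal(as.character(ds2$labels)[1:2], c("NEG", "POS"))
})

test_that("features with missing data are removed, order and samples preserved", {
  m <- matrix(rnorm(30), 6, 5)
  m[4, 3] <- NA
  ds <- omics_dataset(m, rep(c("A", "B"), 3), feature_ids = paste0("g", 1:5))
  out <- drop_missing_features(ds)
  expect_equal(out$feature_ids, paste0("g", c(1, 2, 4, 5)))
  expect_equal(n_samples(out), 6)
  # identity on complete data
  clean <- omics_dataset(matrix(rnorm(30), 6, 5), rep(c("A", "B"), 3))
  expect_identical(drop_missing_features(clean), clean)
  # all features missing -> error
  allna <- omics_dataset(matrix(NA_real_, 6, 2), rep(c("A", "B"), 3))
  expect_error(drop_missing_features(allna), class = "zooselect_error_no_features")
})

test_that("1:1:1 split balances classes to within one sample and is seeded", {
  sim <- toy_dataset(n_pos = 9, n_neg = 6, d = 5, seed = 3)
  sp <- stratified_three_way_split(sim$dataset, seed = 0)
  for (part in list(sp$train, sp$validation, sp$test)) {
    expect_equal(sum(part$labels == "POS"), 3)
    expect_equal(sum(part$labels == "NEG"), 2)
  }
  sp2 <- stratified_three_way_split(sim$dataset, seed = 0)
  expect_identical(sp$assignment, sp2$assignment)

  # P = 10, N = 7: part sizes come from {4,3,3} and {3,2,2}
  sim2 <- toy_dataset(n_pos = 10, n_neg = 7, d = 5, seed = 3)
  sp3 <- stratified_three_way_split(sim2$dataset, seed = 1)
  pos_sizes <- sort(vapply(list(sp3$train, sp3$validation, sp3$test),
                           function(p) sum(p$labels == "POS"), numeric(1)))
  neg_sizes <- sort(vapply(list(sp3$train, sp3$validation, sp3$test),
                           function(p) sum(p$labels == "NEG"), numeric(1)))
  expect_equal(pos_sizes, c(3, 3, 4))
  expect_equal(neg_sizes, c(2, 2, 3))

  tiny <- toy_dataset(n_pos = 2, n_neg = 5, d = 5, seed = 3)
  expect_error(stratified_three_way_split(tiny$dataset, 0),
               class = "zooselect_error_class_too_small")
})

test_that("k-fold indices partition the samples and preserve class ratios", {
  labels <- factor(rep(c("POS", "NEG"), each = 6), levels = c("NEG", "POS"))
  folds <- stratified_kfold_indices(labels, k = 3, seed = 0)
  expect_length(folds, 3)
  tests <- lapply(folds, `[[`, "test")
  expect_setequal(unlist(tests), seq_along(labels))
  for (f in folds) {
    expect_equal(sum(labels[f$test] == "POS"), 2)
    expect_equal(sum(labels[f$test] == "NEG"), 2)
    expect_setequal(c(f$train, f$test), seq_along(labels))
  }
  expect_identical(folds, stratified_kfold_indices(labels, k = 3, seed = 0))
  expect_error(stratified_kfold_indices(factor(c("A", "A", "B", "B")), k = 3),
               class = "zooselect_error_class_too_small")
})

test_that("splits and folds stay disjoint, exhaustive and stratified on random data", {
  for (s in 1:25) {
    n_pos <- sample(5:20, 1)
    n_neg <- sample(5:20, 1)
    sim <- toy_dataset(n_pos, n_neg, d = 3, seed = s)
    sp <- stratified_three_way_split(sim$dataset, seed = s)
    ids <- c(sp$train$sample_ids, sp$validation$sample_ids, sp$test$sample_ids)
    expect_setequal(ids, sim$dataset$sample_ids)
    expect_equal(anyDuplicated(ids), 0L)
    for (lv in c("POS", "NEG")) {
      sizes <- vapply(list(sp$train, sp$validation, sp$test),
                      function(p) sum(p$labels == lv), numeric(1))
      expect_lte(max(sizes) - min(sizes), 1)
    }
  }
})
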