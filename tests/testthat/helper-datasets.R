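# Fixtures built in code: small seeded datasets used across the suite.

# Pure-noise dataset with an optional number of informative features.
toy_dataset <- function(n_pos = 15, n_neg = 15, d = 50, n_informative = 0,
                        effect = 2, seed = 1) {
  generate_synth(synth_spec(n_pos = n_pos, n_neg = n_neg, n_features = d,
                            n_informative = n_informative, effect_size = effect,
                            seed = seed))
}

# Dataset whose feature 1 separates the classes with a wide margin
# (POS values >= 2, NEG values <= -2); all other features are noise.
separable_dataset <- function(n_pos = 30, n_neg = 30, d = 50, seed = 1) {
  sim <- toy_dataset(n_pos, n_neg, d, n_informative = 0, seed = seed)
  ds <- sim$dataset
  vals <- ds$values
  set.seed(seed + 90000)
  vals[ds$labels == "POS", 1] <- 2 + 0.5 * abs(rnorm(n_pos))
  vals[ds$labels == "NEG", 1] <- -2 - 0.5 * abs(rnorm(n_neg))
  omics_dataset(vals, as.character(ds$labels),
                feature_ids = ds$feature_ids, sample_ids = ds$sample_ids)
}

# Write a dataset to a temporary CSV (samples in rows) and a label file.
write_temp_csv <- function(ds) {
  mpath <- tempfile(fileext = ".csv")
  tab <- data.frame(sample_id = ds$sample_ids, ds$values)
  colnames(tab) <- c("sample_id", ds$feature_ids)
  write.csv(tab, mpath, row.names = FALSE, quote = FALSE)
  lpath <- tempfile(fileext = ".csv")
  write.csv(data.frame(sample_id = ds$sample_ids, label = as.character(ds$labels)),
            lpath, row.names = FALSE, quote = FALSE)
  list(matrix = mpath, labels = lpath)
}
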