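#' Construct an omics dataset
#'
#' The universal input container of the package: a numeric sample-by-feature
#' matrix with a binary phenotype per sample. Labels are normalized to a factor
#' with levels `c("NEG", "POS")`. When the input labels are not already
#' `"POS"`/`"NEG"`, the positive class is taken from `positive_label` if given,
#' otherwise the lexicographically larger of the two label strings is treated
#' as positive, which keeps the mapping deterministic without configuration.
#'
#' @param values Numeric matrix, samples in rows, features in columns. `NA`
#'   entries are allowed at construction time and are handled by
#'   [drop_missing_features()].
#' @param labels Vector of length `nrow(values)` with exactly two distinct
#'   values.
#' @param feature_ids,sample_ids Unique identifier vectors; default to the
#'   matrix dimnames or generated `F...`/`S...` ids.
#' @param positive_label Optional label value to treat as the positive class.
#' @return An object of class `OmicsDataset`: a list with elements `values`
#'   (matrix), `labels` (factor, levels `NEG`/`POS`), `feature_ids`,
#'   `sample_ids`.
#' @export
omics_dataset <- function(values, labels, feature_ids = NULL, sample_ids = NULL,
                          positive_label = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  d <- ncol(values)
  if (length(labels) != n) {
    zs_stop(sprintf("labels length (%d) does not match number of samples (%d)",
                    length(labels), n),
            "zooselect_error_dimension_mismatch")
  }
  lab <- as.character(labels)
  classes <- sort(unique(lab))
  if (length(classes) != 2) {
    zs_stop(sprintf("labels not binary: found %d distinct values", length(classes)),
            "zooselect_error_labels_not_binary")
  }
  if (is.null(positive_label)) {
    positive_label <- if (setequal(classes, c("NEG", "POS"))) "POS" else classes[2L]
  }
  if (!positive_label %in% classes) {
    zs_stop("positive_label does not occur among the labels",
            "zooselect_error_labels_not_binary")
  }
  y <- factor(ifelse(lab == positive_label, "POS", "NEG"), levels = c("NEG", "POS"))
  feature_ids <- feature_ids %||% colnames(values) %||% sprintf("F%05d", seq_len(d))
  sample_ids <- sample_ids %||% rownames(values) %||% sprintf("S%04d", seq_len(n))
  if (length(feature_ids) != d || anyDuplicated(feature_ids)) {
    zs_stop("feature_ids must be unique and match the number of features",
            "zooselect_error_dimension_mismatch")
  }
  if (length(sample_ids) != n || anyDuplicated(sample_ids)) {
    zs_stop("sample_ids must be unique and match the number of samples",
            "zooselect_error_dimension_mismatch")
  }
  dimnames(values) <- NULL
  structure(list(values = values,
                 labels = y,
                 feature_ids = as.character(feature_ids),
                 sample_ids = as.character(sample_ids)),
            class = "OmicsDataset")
}

#' @export
print.OmicsDataset <- function(x, ...) {
  cat(sprintf("<OmicsDataset> %d samples x %d features (POS = %d, NEG = %d)\n",
              n_samples(x), n_features(x),
              sum(x$labels == "POS"), sum(x$labels == "NEG")))
  invisible(x)
}

#' Dataset dimensions
#'
#' @param ds An [omics_dataset()].
#' @return Integer count of samples or features.
#' @export
n_samples <- function(ds) nrow(ds$values)

#' @rdname n_samples
#' @export
n_features <- function(ds) ncol(ds$values)

#' Subset a dataset by feature or sample indices
#'
#' Order of `idx` is preserved, so these double as reordering operations.
#'
#' @param ds An [omics_dataset()].
#' @param idx Integer indices.
#' @return A new `OmicsDataset`.
#' @export
subset_features <- function(ds, idx) {
  structure(list(values = ds$values[, idx, drop = FALSE],
                 labels = ds$labels,
                 feature_ids = ds$feature_ids[idx],
                 sample_ids = ds$sample_ids),
            class = "OmicsDataset")
}

#' @rdname subset_features
#' @export
subset_samples <- function(ds, idx) {
  structure(list(values = ds$values[idx, , drop = FALSE],
                 labels = ds$labels[idx],
                 feature_ids = ds$feature_ids,
                 sample_ids = ds$sample_ids[idx]),
            class = "OmicsDataset")
}

# counts per class, used by the splitters for precondition checks
class_counts <- function(ds) table(ds$labels)
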