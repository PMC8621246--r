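#' Load an omics matrix with binary labels from delimited text
#'
#' Reads a CSV/TSV matrix (first column = row identifiers, header = column
#' identifiers) together with a label source and returns a cleaned
#' [omics_dataset()]. Lines starting with `"!"` are skipped, so GEO
#' series-matrix-style tables can be ingested directly (parsing only; nothing
#' is downloaded). Any cell that does not parse as a number counts as missing;
#' by default features containing missing values are removed
#' ([drop_missing_features()]).
#'
#' @param matrix_path Path to the delimited matrix. The delimiter is inferred
#'   from the extension (`.csv` comma, otherwise tab) unless `sep` is given.
#' @param labels One of: a path to a two-column delimited file
#'   (`sample_id`, `label`, no header required); a vector of labels, one per
#'   sample in matrix order; or the name of a single row/column of the matrix
#'   holding the labels (it is removed from the numeric matrix).
#' @param orientation `"features"` (default; rows are features, the GEO
#'   series-matrix convention) or `"samples"` (rows are samples).
#' @param sep Optional field separator overriding extension-based detection.
#' @param positive_label Optional explicit positive class, see
#'   [omics_dataset()].
#' @param clean If `TRUE` (default) drop features with missing entries.
#' @return An [omics_dataset()], oriented samples x features.
#' @export
load_dataset <- function(matrix_path, labels,
                         orientation = c("features", "samples"),
                         sep = NULL, positive_label = NULL, clean = TRUE) {
  orientation <- match.arg(orientation)
  if (!is.character(matrix_path) || length(matrix_path) != 1 || !file.exists(matrix_path)) {
    zs_stop(sprintf("cannot read matrix file: %s", paste(matrix_path, collapse = ", ")),
            "zooselect_error_unreadable_file")
  }
  sep <- sep %||% guess_sep(matrix_path)
  raw <- tryCatch(
    utils::read.table(matrix_path, sep = sep, header = TRUE, row.names = 1,
                      comment.char = "!", check.names = FALSE, quote = "\"",
                      stringsAsFactors = FALSE),
    error = function(e) zs_stop(sprintf("cannot read matrix file: %s", conditionMessage(e)),
                                "zooselect_error_unreadable_file"))
  m <- as.matrix(raw)

  label_vec <- NULL
  if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
    label_vec <- read_label_file(labels)
  } else if (is.character(labels) && length(labels) == 1 &&
             (labels %in% rownames(m) || labels %in% colnames(m))) {
    if (labels %in% rownames(m) && orientation == "features") {
      label_vec <- stats::setNames(as.character(m[labels, ]), colnames(m))
      m <- m[setdiff(rownames(m), labels), , drop = FALSE]
    } else if (labels %in% colnames(m) && orientation == "samples") {
      label_vec <- stats::setNames(as.character(m[, labels]), rownames(m))
      m <- m[, setdiff(colnames(m), labels), drop = FALSE]
    }
  }

  vals <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m)))
  if (orientation == "features") vals <- t(vals)

  if (is.null(label_vec)) {
    if (length(labels) != nrow(vals)) {
      zs_stop(sprintf("found %d labels for %d samples", length(labels), nrow(vals)),
              "zooselect_error_dimension_mismatch")
    }
    label_vec <- as.character(labels)
  } else {
    sid <- rownames(vals) %||% as.character(seq_len(nrow(vals)))
    if (!all(sid %in% names(label_vec))) {
      zs_stop("label file does not cover every sample id in the matrix",
              "zooselect_error_dimension_mismatch")
    }
    label_vec <- unname(label_vec[sid])
  }

  ds <- omics_dataset(vals, label_vec, positive_label = positive_label)
  if (clean && anyNA(ds$values)) ds <- drop_missing_features(ds)
  ds
}

guess_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

read_label_file <- function(path) {
  tab <- tryCatch(
    utils::read.table(path, sep = guess_sep(path), header = FALSE,
                      comment.char = "!", stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) zs_stop(sprintf("cannot read label file: %s", conditionMessage(e)),
                                "zooselect_error_unreadable_file"))
  if (ncol(tab) < 2) {
    zs_stop("label file must have two columns: sample_id, label",
            "zooselect_error_unreadable_file")
  }
  # tolerate a header line such as "sample_id<TAB>label"
  if (nrow(tab) > 1 && tolower(tab[1, 2]) %in% c("label", "class", "phenotype")) {
    tab <- tab[-1, , drop = FALSE]
  }
  stats::setNames(tab[[2]], tab[[1]])
}

#' Remove features containing missing values
#'
#' Every feature with at least one missing entry is dropped; samples and the
#' relative order of the surviving features are unchanged.
#'
#' @param ds An [omics_dataset()].
#' @return An `OmicsDataset` without missing entries.
#' @export
drop_missing_features <- function(ds) {
  keep <- colSums(is.na(ds$values)) == 0
  if (!any(keep)) {
    zs_stop("no features remain after removing features with missing data",
            "zooselect_error_no_features")
  }
  if (all(keep)) return(ds)
  subset_features(ds, which(keep))
}

#' Stratified 1:1:1 split into training, validation and test sets
#'
#' Samples of each class are shuffled with the seeded generator and dealt
#' round-robin into the three parts (train, validation, test), which
#' guarantees per-class part sizes within one sample of each other.
#'
#' @param ds An [omics_dataset()] with at least 3 samples per class.
#' @param seed Integer seed controlling the within-class shuffle.
#' @return A list of class `SplitTriple` with elements `train`, `validation`,
#'   `test` (each an `OmicsDataset`) and an `assignment` factor mapping every
#'   sample to its part.
#' @export
stratified_three_way_split <- function(ds, seed = 0) {
  part_of <- stratified_assignment(ds$labels, 3, seed, min_per_class = 3)
  parts <- c("train", "validation", "test")
  out <- lapply(1:3, function(p) subset_samples(ds, which(part_of == p)))
  names(out) <- parts
  out$assignment <- stats::setNames(factor(parts[part_of], levels = parts), ds$sample_ids)
  class(out) <- "SplitTriple"
  out
}

#' @export
print.SplitTriple <- function(x, ...) {
  cat(sprintf("<SplitTriple> train %d / validation %d / test %d samples\n",
              n_samples(x$train), n_samples(x$validation), n_samples(x$test)))
  invisible(x)
}

# Shuffle each class with the seeded RNG, then deal round-robin into k groups.
stratified_assignment <- function(labels, k, seed, min_per_class = k) {
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts < min_per_class)) {
    zs_stop(sprintf("each class needs at least %d samples (found %s)",
                    min_per_class, paste(counts, collapse = "/")),
            "zooselect_error_class_too_small")
  }
  with_seed(seed, {
    grp <- integer(length(labels))
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      idx <- idx[sample.int(length(idx))]
      grp[idx] <- rep_len(seq_len(k), length(idx))
    }
    grp
  })
}

#' Stratified k-fold cross-validation indices
#'
#' Each sample lands in exactly one test fold and the per-fold class ratio
#' matches the global ratio to within one sample. Defaults follow the
#' stratified three-fold protocol with seed 0.
#'
#' @param labels Binary label vector/factor.
#' @param k Number of folds (default 3).
#' @param seed Integer seed (default 0).
#' @return List of `k` elements, each `list(train = <indices>, test = <indices>)`.
#' @export
stratified_kfold_indices <- function(labels, k = 3, seed = 0) {
  fold <- stratified_assignment(labels, k, seed, min_per_class = k)
  lapply(seq_len(k), function(f) {
    list(train = which(fold != f), test = which(fold == f))
  })
}

#' Write a dataset and split manifest as TSV
#'
#' @param ds An [omics_dataset()].
#' @param path Output file. The matrix is written features-in-rows with a
#'   leading `feature_id` column; labels as a `sample_id`/`label` table.
#' @export
write_dataset_tsv <- function(ds, path) {
  tab <- data.frame(feature_id = ds$feature_ids,
                    t(ds$values), check.names = FALSE)
  colnames(tab) <- c("feature_id", ds$sample_ids)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_tsv
#' @export
write_labels_tsv <- function(ds, path) {
  utils::write.table(data.frame(sample_id = ds$sample_ids,
                                label = as.character(ds$labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param split A `SplitTriple` from [stratified_three_way_split()].
#' @rdname write_dataset_tsv
#' @export
write_split_manifest <- function(split, path) {
  utils::write.table(data.frame(sample_id = names(split$assignment),
                                part = as.character(split$assignment)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
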