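#' Specify a synthetic "large p small n" dataset
#'
#' Defines a Gaussian mean-shift simulation: every feature is standard normal
#' noise except a small planted set whose class means are shifted by
#' `+effect_size/2` in the positive class and `-effect_size/2` in the negative
#' class, so the planted between-class mean difference equals `effect_size`
#' noise standard deviations and the pooled mean stays at zero. Planted
#' features may come in blocks sharing a latent factor, giving pairwise
#' correlation `rho` within a block — redundancy for elimination stages to
#' remove.
#'
#' Defaults encode the package's reference study conditions: 90 samples
#' (45/45), 2000 features, 10 informative at effect size 2.
#'
#' @param n_pos,n_neg Samples per class.
#' @param n_features Total feature count.
#' @param n_informative Number of planted informative features.
#' @param effect_size Between-class mean shift in noise-SD units (>= 0).
#' @param correlated_block_size Planted features per correlated block (1 =
#'   independent planted features).
#' @param rho Within-block pairwise correlation, in `[0, 1)`.
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @return A list of class `SynthSpec`.
#' @export
synth_spec <- function(n_pos = 45, n_neg = 45, n_features = 2000,
                       n_informative = 10, effect_size = 2,
                       correlated_block_size = 1, rho = 0, seed = 0) {
  if (n_informative > n_features) {
    zs_stop("n_informative cannot exceed n_features", "zooselect_error_invalid_spec")
  }
  if (effect_size < 0 || rho < 0 || rho >= 1 || correlated_block_size < 1 ||
      n_pos < 1 || n_neg < 1 || n_features < 1) {
    zs_stop("invalid synthetic-data specification", "zooselect_error_invalid_spec")
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size,
                 correlated_block_size = as.integer(correlated_block_size),
                 rho = rho, seed = as.integer(seed)),
            class = "SynthSpec")
}

#' Generate a synthetic dataset with planted informative features
#'
#' @param spec A [synth_spec()].
#' @return List with `dataset` (an [omics_dataset()]) and `planted` (sorted
#'   integer indices of the informative features — the ground truth).
#' @export
generate_synth <- function(spec) {
  stopifnot(inherits(spec, "SynthSpec"))
  with_seed(spec$seed, {
    n <- spec$n_pos + spec$n_neg
    p <- spec$n_features
    x <- matrix(stats::rnorm(n * p), n, p)
    planted <- sort(sample.int(p, spec$n_informative))
    if (spec$correlated_block_size > 1 && spec$rho > 0 && spec$n_informative > 1) {
      blocks <- split(planted, ceiling(seq_along(planted) / spec$correlated_block_size))
      for (b in blocks) {
        if (length(b) < 2) next
        z <- stats::rnorm(n)
        x[, b] <- sqrt(spec$rho) * z + sqrt(1 - spec$rho) * x[, b]
      }
    }
    y <- rep(c("POS", "NEG"), c(spec$n_pos, spec$n_neg))
    if (spec$n_informative > 0 && spec$effect_size > 0) {
      shift <- spec$effect_size / 2
      x[y == "POS", planted] <- x[y == "POS", planted] + shift
      x[y == "NEG", planted] <- x[y == "NEG", planted] - shift
    }
    ds <- omics_dataset(x, y,
                        feature_ids = sprintf("F%05d", seq_len(p)),
                        sample_ids = sprintf("S%04d", seq_len(n)))
    list(dataset = ds, planted = planted)
  })
}

#' Write a synthetic dataset in the formats the loader reads
#'
#' Produces `matrix.tsv` (features in rows), `labels.tsv` and
#' `planted_truth.tsv` under `dir`.
#'
#' @param sim Output of [generate_synth()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_tsv <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dataset_tsv(sim$dataset, file.path(dir, "matrix.tsv"))
  write_labels_tsv(sim$dataset, file.path(dir, "labels.tsv"))
  utils::write.table(data.frame(feature_id = sim$dataset$feature_ids[sim$planted],
                                index = sim$planted),
                     file.path(dir, "planted_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
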