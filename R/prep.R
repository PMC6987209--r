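#' Filter features by per-group presence
#'
#' Keeps a feature iff it has at least `min_present` non-missing values in at
#' least one experimental group — the standard rule for combining TMT runs
#' (e.g. "six out of eight replicates of one group").
#'
#' @param m an [omics_matrix()].
#' @param ann sample annotation covering all columns of `m`.
#' @param min_present required observations within a single group.
#' @return the filtered `omics_matrix` (same samples, subset of features).
#' @export
filter_by_group_presence <- function(m, ann, min_present = 6) {
  a <- ann_for(ann, m)
  gs <- table(a$group)
  if (min_present > min(gs))
    stop("min_present exceeds the smallest group size (", min(gs), ")")
  obs <- !is.na(unclass(m))
  keep <- Reduce(`|`, lapply(unique(a$group), function(g) {
    rowSums(obs[, a$group == g, drop = FALSE]) >= min_present
  }))
  omics_matrix(unclass(m)[keep, , drop = FALSE], scale = om_scale(m))
}

#' Normalize on total intensity and scale to a target channel average
#'
#' Two-step TMT-style normalization on linear intensities: each sample column
#' is divided by its total (missing values ignored) and multiplied by the mean
#' of totals, then every column is rescaled so its mean of observed values
#' equals `target_mean` (default 100, the "channel average of 100"
#' convention). Within-column ratios are preserved.
#'
#' @param m linear-scale [omics_matrix()], non-negative values.
#' @param target_mean target per-column mean of observed values.
#' @return normalized linear-scale `omics_matrix`.
#' @export
normalize_total_and_scale <- function(m, target_mean = 100) {
  if (om_scale(m) != "linear") stop("total-intensity normalization needs a linear-scale matrix")
  v <- unclass(m)
  tot <- colSums(v, na.rm = TRUE)
  if (any(tot == 0)) stop("column(s) with zero total intensity: ",
                          paste(colnames(v)[tot == 0], collapse = ", "))
  v <- sweep(v, 2, tot, "/") * mean(tot)
  cm <- colMeans(v, na.rm = TRUE)
  v <- sweep(v, 2, target_mean / cm, "*")
  omics_matrix(v, scale = "linear")
}

#' Impute left-censored missing values from a downshifted normal
#'
#' Missing entries of column j are replaced by draws from
#' `Normal(mean_j - downshift * sd_j, (width * sd_j)^2)` where `mean_j`,
#' `sd_j` are computed over the observed log2 values of that column — the
#' Perseus convention for intensity-dependent (MNAR) missingness.
#'
#' @param m log2-scale [omics_matrix()].
#' @param downshift location shift in units of the column sd (e.g. 2.5 for
#'   liver, 1.8 for plasma).
#' @param width imputation sd in units of the column sd (e.g. 0.2 / 0.3).
#' @param seed integer seed; same seed reproduces identical draws.
#' @return fully observed log2-scale `omics_matrix`.
#' @export
impute_downshifted <- function(m, downshift = 2.5, width = 0.2, seed = 1L) {
  if (om_scale(m) != "log2") stop("imputation operates on log2-scale matrices")
  v <- unclass(m)
  nobs <- colSums(!is.na(v))
  if (any(nobs < 2)) stop("column(s) with < 2 observed values cannot be imputed")
  with_seed(seed, {
    for (j in seq_len(ncol(v))) {
      miss <- is.na(v[, j])
      if (!any(miss)) next
      mu <- mean(v[, j], na.rm = TRUE)
      s <- stats::sd(v[, j], na.rm = TRUE)
      v[miss, j] <- stats::rnorm(sum(miss), mu - downshift * s, width * s)
    }
    omics_matrix(v, scale = "log2")
  })
}

#' Mean-center each feature within each batch
#'
#' Removes additive batch (run) effects from a fully observed log-scale
#' matrix: within every batch, each feature's values are centered on their
#' within-batch mean, so per-feature within-batch means are exactly zero.
#'
#' @param m log2-scale, fully observed [omics_matrix()].
#' @param ann annotation with a `batch` column covering all samples of `m`.
#' @return centered `omics_matrix`.
#' @export
center_batches <- function(m, ann) {
  if (om_scale(m) != "log2") stop("batch centering operates on log-scale matrices")
  if (anyNA(m)) stop("matrix must be fully observed (impute first)")
  a <- ann_for(ann, m)
  if (anyNA(a$batch)) stop("batch is NA for some samples of the matrix")
  v <- unclass(m)
  for (b in unique(a$batch)) {
    sel <- a$batch == b
    if (sum(sel) == 1) warning("batch ", b, " has a single sample; centering sets it to 0")
    v[, sel] <- v[, sel, drop = FALSE] - rowMeans(v[, sel, drop = FALSE])
  }
  omics_matrix(v, scale = "log2")
}

#' Counts per million and expressed-gene filter
#'
#' Converts a count matrix to CPM (each column sums to 1e6) and flags a gene
#' as expressed iff its CPM is at least `threshold` in strictly more than
#' half the samples of at least one experimental group ("majority" read as
#' strict).
#'
#' @param counts counts-scale [omics_matrix()].
#' @param ann sample annotation.
#' @param threshold CPM threshold (default 1).
#' @return list with `cpm` (linear-scale `omics_matrix`) and `expressed`
#'   (named logical per gene).
#' @export
cpm_and_expressed_filter <- function(counts, ann, threshold = 1) {
  if (om_scale(counts) != "counts") stop("expected a counts matrix")
  v <- unclass(counts)
  tot <- colSums(v, na.rm = TRUE)
  if (any(tot == 0)) stop("zero-count sample column(s): ",
                          paste(colnames(v)[tot == 0], collapse = ", "))
  cpm <- sweep(v, 2, tot, "/") * 1e6
  a <- ann_for(ann, counts)
  expressed <- Reduce(`|`, lapply(unique(a$group), function(g) {
    sel <- a$group == g
    rowSums(cpm[, sel, drop = FALSE] >= threshold, na.rm = TRUE) > sum(sel) / 2
  }))
  names(expressed) <- rownames(v)
  list(cpm = omics_matrix(cpm, scale = "linear"), expressed = expressed)
}
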