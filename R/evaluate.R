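#' Sample PCA scores of an expression matrix
#'
#' Features (rows) are mean-centered and sample scores computed from the
#' singular value decomposition — exact PCA on a fully observed (imputed)
#' matrix. Each component's sign is fixed so that its feature loading of
#' largest magnitude is positive, making scores reproducible.
#'
#' @param m fully observed log2-scale [omics_matrix()] (features x samples).
#' @param k number of components, at most `min(dim(m))`.
#' @return list: `scores` (samples x k), `var_explained` (length-k fractions),
#'   `loadings` (features x k).
#' @export
pca_scores <- function(m, k = 3) {
  if (anyNA(m)) stop("matrix must be fully observed (impute first)")
  v <- unclass(m)
  if (k > min(dim(v))) stop("k exceeds matrix rank bound")
  vc <- v - rowMeans(v)
  sv <- svd(vc, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    l <- sv$u[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$v[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k), 2, flip, "*")
  loadings <- sweep(sv$u[, seq_len(k), drop = FALSE], 2, flip, "*")
  dimnames(scores) <- list(colnames(v), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(rownames(v), paste0("PC", seq_len(k)))
  list(scores = scores, var_explained = sv$d[seq_len(k)]^2 / sum(sv$d^2),
       loadings = loadings)
}

#' Regress liver PCA components on a plasma marker
#'
#' Simple linear regression of each of the first `components` PC scores on
#' the per-sample plasma intensity of a marker (marker as predictor). For
#' simple regression, r-squared equals the squared Pearson correlation; the
#' two-sided p-value of the slope is reported.
#'
#' @param plasma named numeric vector of per-sample marker intensities.
#' @param pca result of [pca_scores()].
#' @param components PC indices to regress (default 1:3).
#' @return data frame: component, r2, p, n.
#' @export
marker_pc_regression <- function(plasma, pca, components = 1:3) {
  shared <- intersect(names(plasma), rownames(pca$scores))
  if (length(shared) < 3) stop("fewer than 3 shared samples")
  x <- plasma[shared]
  rows <- lapply(components, function(j) {
    y <- pca$scores[shared, j]
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    p <- if (nrow(sm$coefficients) < 2) NA_real_ else sm$coefficients[2, 4]
    data.frame(component = j, r2 = sm$r.squared, p = p, n = length(shared))
  })
  do.call(rbind, rows)
}

#' Tissue-enrichment factor from a tissue expression panel
#'
#' For each gene, the enrichment factor of a tissue is its median expression
#' in that tissue divided by a gene-level denominator: the median of the
#' per-tissue medians (default) or their geometric mean
#' (`denominator = "geomean"`). The top two enriched tissues per gene are
#' reported.
#'
#' @param panel numeric matrix, genes x tissues, of per-tissue median
#'   expression (non-negative).
#' @param denominator "median" (median of medians) or "geomean".
#' @return list: `enrichment` (genes x tissues matrix; NA with a flag where
#'   the denominator is 0), `top2` (data frame gene, tissue1, factor1,
#'   tissue2, factor2), `zero_denominator` (gene ids flagged).
#' @export
tissue_enrichment <- function(panel, denominator = c("median", "geomean")) {
  denominator <- match.arg(denominator)
  if (ncol(panel) < 2) stop("need >= 2 tissues")
  if (any(panel < 0, na.rm = TRUE)) stop("medians must be >= 0")
  den <- apply(panel, 1, function(x) {
    if (denominator == "median") stats::median(x, na.rm = TRUE)
    else exp(mean(log(x), na.rm = TRUE))
  })
  bad <- !is.finite(den) | den == 0
  enr <- sweep(panel, 1, ifelse(bad, NA, den), "/")
  top2 <- t(apply(enr, 1, function(x) {
    o <- order(x, decreasing = TRUE)
    c(o[1], x[o[1]], o[2], x[o[2]])
  }))
  top2 <- data.frame(gene = rownames(panel),
                     tissue1 = colnames(panel)[top2[, 1]], factor1 = top2[, 2],
                     tissue2 = colnames(panel)[top2[, 3]], factor2 = top2[, 4],
                     stringsAsFactors = FALSE)
  list(enrichment = enr, top2 = top2,
       zero_denominator = rownames(panel)[bad])
}
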