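#' Per-feature correlation with the liver-fibrosis score
#'
#' Pearson correlation (Spearman optionally) between each feature's
#' per-sample expression and the ordinal fibrosis score, treated as numeric.
#' Samples with missing expression are excluded pairwise. Features with
#' constant expression (or a constant score) get `r = NA`, `r2 = 0` and a
#' `degenerate` flag.
#'
#' @param m an [omics_matrix()] on any scale (values used as-is; pass FPKM /
#'   relative intensity / log2 as appropriate).
#' @param ann sample annotation with `fibrosis_score`.
#' @param method "pearson" (default, the linear-correlation convention) or
#'   "spearman".
#' @return data frame: feature_id, r, r2, p, n, degenerate.
#' @export
histology_correlation <- function(m, ann, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  a <- ann_for(ann, m)
  y <- as.numeric(a$fibrosis_score)
  v <- unclass(m)
  if (method == "spearman") y <- rank(y)
  res <- t(apply(v, 1, function(x) {
    if (method == "spearman") x <- rank(x, na.last = "keep")
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3) return(c(NA, 0, NA, n, 1))
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(c(NA, 0, NA, n, 1))
    r <- stats::cor(x[ok], y[ok])
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    c(r, r^2, p, n, 0)
  }))
  data.frame(feature_id = rownames(v), r = res[, 1], r2 = res[, 2],
             p = res[, 3], n = as.integer(res[, 4]),
             degenerate = res[, 5] == 1, stringsAsFactors = FALSE)
}

#' Cross-matrix concordance classification
#'
#' Joins the regulation calls of two contrasts (e.g. liver RNA vs liver
#' protein) over their shared features and classifies each pair:
#' `co_regulated` (both significant, same sign), `anti_regulated` (both
#' significant, opposite signs), `single` (exactly one significant), `none`.
#' The summary reports class counts and the Pearson correlation of the shared
#' log2 fold changes.
#'
#' @param deA,deB data frames from [call_regulated()]; feature ids must be on
#'   a shared namespace (map proteins to genes first).
#' @return list: `table` (feature_id, call_a, call_b, class), `summary`
#'   (overlap n, counts per class, lfc_pearson_r).
#' @export
concordance_classes <- function(deA, deB) {
  shared <- intersect(deA$feature_id, deB$feature_id)
  if (!length(shared)) stop("no shared features between the two contrasts")
  ia <- match(shared, deA$feature_id); ib <- match(shared, deB$feature_id)
  ca <- as.character(deA$call[ia]); cb <- as.character(deB$call[ib])
  siga <- ca != "none"; sigb <- cb != "none"
  class <- ifelse(siga & sigb, ifelse(ca == cb, "co_regulated", "anti_regulated"),
                  ifelse(siga | sigb, "single", "none"))
  tab <- data.frame(feature_id = shared, call_a = ca, call_b = cb,
                    class = class, log2fc_a = deA$log2fc[ia],
                    log2fc_b = deB$log2fc[ib], stringsAsFactors = FALSE)
  counts <- table(factor(class, levels = c("co_regulated", "anti_regulated", "single", "none")))
  list(table = tab,
       summary = list(overlap_n = length(shared),
                      counts = as.list(counts),
                      lfc_pearson_r = stats::cor(tab$log2fc_a, tab$log2fc_b,
                                                 use = "pairwise.complete.obs")))
}
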