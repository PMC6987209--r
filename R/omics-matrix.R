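#' Feature-by-sample expression matrix with missing-value support
#'
#' An `omics_matrix` is a plain numeric matrix (rows = features, columns =
#' samples, `NA` = missing) carrying a `scale` attribute that declares how the
#' values are to be read: `"counts"` (non-negative integers, RNA-Seq),
#' `"linear"` (non-negative intensities) or `"log2"` (log2-transformed
#' intensities). Preprocessing operations check the tag so that, e.g.,
#' total-intensity normalization is never applied to log-space data.
#'
#' @param values numeric matrix with rownames (feature ids) and colnames
#'   (sample ids); `NA` encodes a missing measurement.
#' @param scale one of `"counts"`, `"linear"`, `"log2"`.
#' @return an object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, scale = c("log2", "linear", "counts")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (scale %in% c("counts", "linear") && any(values < 0, na.rm = TRUE))
    stop("negative values are not allowed on a ", scale, " scale")
  structure(values, scale = scale, class = c("omics_matrix", "matrix", "array"))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s scale]: %d features x %d samples, %.1f%% missing\n",
              attr(x, "scale"), nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

om_scale <- function(m) {
  s <- attr(m, "scale")
  if (is.null(s)) stop("matrix has no scale tag; build it with omics_matrix()")
  s
}

#' Log2-transform a linear-scale matrix
#'
#' @param m linear-scale `omics_matrix` (strictly positive observed values).
#' @param pseudocount added before the log; default 0.
#' @return log2-scale `omics_matrix`.
#' @export
log2_transform <- function(m, pseudocount = 0) {
  if (om_scale(m) == "log2") stop("matrix is already on log2 scale")
  v <- unclass(m) + pseudocount
  if (any(v <= 0, na.rm = TRUE)) stop("non-positive values cannot be log2-transformed")
  omics_matrix(log2(v), scale = "log2")
}

#' Validate a sample annotation against a matrix
#'
#' The annotation is a data frame with columns `sample_id`, `group`, `week`,
#' `batch`, `fibrosis_score`. Every matrix column must be annotated.
#'
#' @param ann annotation data frame.
#' @param m optional `omics_matrix` whose samples must all appear.
#' @return the annotation, invisibly, after validation.
#' @export
validate_annotation <- function(ann, m = NULL) {
  needed <- c("sample_id", "group", "week", "batch", "fibrosis_score")
  miss <- setdiff(needed, names(ann))
  if (length(miss)) stop("annotation lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$sample_id)) stop("duplicate sample ids in annotation")
  if (any(ann$fibrosis_score < 0, na.rm = TRUE)) stop("fibrosis_score must be >= 0")
  if (!is.null(m)) {
    unk <- setdiff(colnames(m), ann$sample_id)
    if (length(unk)) stop("samples missing from annotation: ", paste(unk, collapse = ", "))
  }
  invisible(ann)
}

ann_for <- function(ann, m) {
  validate_annotation(ann, m)
  ann[match(colnames(m), ann$sample_id), , drop = FALSE]
}

#' Read / write expression matrices as TSV
#'
#' TSV layout: first column `feature_id`, remaining columns one per sample,
#' missing values written as `NA`.
#'
#' @param path file path.
#' @param scale scale tag to attach on read.
#' @return `read_omics_tsv`: an `omics_matrix`; `write_omics_tsv`: the path,
#'   invisibly.
#' @export
read_omics_tsv <- function(path, scale = c("log2", "linear", "counts")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "feature_id") stop("first column must be `feature_id`")
  v <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- df$feature_id
  omics_matrix(v, scale = scale)
}

#' @rdname read_omics_tsv
#' @param m `omics_matrix` to write.
#' @export
write_omics_tsv <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), format_num(unclass(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# 6-significant-digit formatting for byte-stable table diffs
format_num <- function(x) {
  if (is.matrix(x)) {
    out <- apply(x, 2, function(col) ifelse(is.na(col), "NA", formatC(signif(col, 6), format = "g", digits = 6)))
    rownames(out) <- rownames(x)
    return(out)
  }
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}

write_table_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) format_num(col))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
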