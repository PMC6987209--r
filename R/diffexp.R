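## Differential statistics: pooled t-test, BH, permutation FDR, DE calls,
## the dge score, time-profile clustering, Fisher overrepresentation.

row_group_t <- function(v, selA, selB, welch = FALSE) {
  nA <- rowSums(!is.na(v[, selA, drop = FALSE]))
  nB <- rowSums(!is.na(v[, selB, drop = FALSE]))
  mA <- rowMeans(v[, selA, drop = FALSE], na.rm = TRUE)
  mB <- rowMeans(v[, selB, drop = FALSE], na.rm = TRUE)
  ssA <- rowSums((v[, selA, drop = FALSE] - mA)^2, na.rm = TRUE)
  ssB <- rowSums((v[, selB, drop = FALSE] - mB)^2, na.rm = TRUE)
  if (welch) {
    vA <- ssA / (nA - 1); vB <- ssB / (nB - 1)
    se2 <- vA / nA + vB / nB
    df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  } else {
    df <- nA + nB - 2
    sp2 <- (ssA + ssB) / df
    se2 <- sp2 * (1 / nA + 1 / nB)
  }
  t <- (mB - mA) / sqrt(se2)
  p <- 2 * stats::pt(-abs(t), df)
  list(lfc = mB - mA, t = t, p = p, df = df)
}

#' Per-feature two-group differential statistics
#'
#' Two-sided pooled-variance Student t-test per feature on a log2-scale
#' matrix; log2 fold change is `mean(groupB) - mean(groupA)`. Missing values
#' are dropped per feature. Features with zero pooled variance get `NA`
#' statistics with a warning. Benjamini-Hochberg adjusted p-values are
#' included.
#'
#' @param m log2-scale [omics_matrix()].
#' @param ann sample annotation.
#' @param contrast character pair `c(groupA, groupB)`; the reported fold
#'   change is B vs A.
#' @param contrast_id label stored in the result (e.g. "liver_protein").
#' @param welch use Welch's unequal-variance t instead of the pooled t.
#' @return data frame: feature_id, contrast, log2fc, t, p, padj.
#' @export
differential_stats <- function(m, ann, contrast, contrast_id = paste(contrast, collapse = "_vs_"),
                               welch = FALSE) {
  if (om_scale(m) != "log2") stop("differential statistics expect a log2-scale matrix")
  a <- ann_for(ann, m)
  selA <- a$group == contrast[1]
  selB <- a$group == contrast[2]
  if (sum(selA) < 2 || sum(selB) < 2) stop("need >= 2 samples per group")
  st <- row_group_t(unclass(m), selA, selB, welch = welch)
  bad <- !is.finite(st$t)
  if (any(bad)) {
    warning(sum(bad), " feature(s) with zero variance: statistics reported as NA")
    st$t[bad] <- NA_real_; st$p[bad] <- NA_real_
  }
  data.frame(feature_id = rownames(m), contrast = contrast_id,
             log2fc = st$lfc, t = st$t, p = st$p,
             padj = bh_adjust(st$p), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in [0, 1] (NA passed through).
#' @return adjusted p-values, monotone and capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# |t| statistics for B relabelings via group-sum matrix products on a fully
# observed matrix (columns ordered group A first). Balanced permutations draw
# half of each pseudo-group from each true group, keeping genuine effects out
# of the null distribution (the SAM convention).
perm_abs_t <- function(v, nA, n, n_perm, seed, balanced = TRUE) {
  nB <- n - nA
  if (balanced) {
    kA <- max(nA - nB, min(nA, round(nA * nA / n)))   # from true A into pseudo-A
    n_arr <- choose(nA, kA) * choose(nB, nA - kA)
  } else {
    n_arr <- choose(n, nA)
  }
  exhaustive <- n_arr <= n_perm
  combos <- if (exhaustive && balanced) {
    ca <- utils::combn(nA, kA)
    cb <- utils::combn(nB, nA - kA) + nA
    do.call(cbind, lapply(seq_len(ncol(ca)), function(i)
      rbind(matrix(ca[, i], nrow(ca), ncol(cb)), cb)))
  } else if (exhaustive) {
    utils::combn(n, nA)
  } else if (balanced) {
    with_seed(seed, replicate(n_perm, c(sample.int(nA, kA),
                                        nA + sample.int(nB, nA - kA))))
  } else {
    with_seed(seed, replicate(n_perm, sample.int(n, nA)))
  }
  B <- ncol(combos)
  W <- matrix(0, n, B)
  W[cbind(as.vector(combos), rep(seq_len(B), each = nA))] <- 1
  SA <- v %*% W; SSA <- (v * v) %*% W
  ST <- rowSums(v); SST <- rowSums(v * v)
  SB <- ST - SA; SSB <- SST - SSA
  ssA <- SSA - SA^2 / nA
  ssB <- SSB - SB^2 / nB
  t <- (SB / nB - SA / nA) / sqrt((ssA + ssB) / (n - 2) * (1 / nA + 1 / nB))
  list(abs_t = abs(t), n_perm = B, exhaustive = exhaustive)
}

#' Permutation-based false discovery rate (SAM-style, s0 = 0)
#'
#' For each feature with observed statistic |t_i|, the q-value is the mean
#' over label permutations of the number of null |t| values at or above
#' |t_i|, divided by the observed count at or above |t_i|, then made
#' monotone non-increasing in |t| (a running minimum swept from the least
#' significant feature toward the largest |t|) and capped at 1. Label
#' permutations keep group sizes fixed and are balanced by default (each
#' pseudo-group drawing half its members from each true group, so genuine
#' effects do not inflate the null); if fewer distinct arrangements exist
#' than `n_perm`, all are enumerated and the result is seed-independent.
#'
#' @param m log2-scale, fully observed [omics_matrix()].
#' @param ann sample annotation.
#' @param contrast character pair `c(groupA, groupB)`.
#' @param n_perm number of permutations (>= 100 recommended).
#' @param seed integer seed for the permutation draws.
#' @param balanced use balanced permutations (default) or unrestricted ones.
#' @return named numeric vector of q-values per feature.
#' @export
permutation_fdr <- function(m, ann, contrast, n_perm = 1000, seed = 1L,
                            balanced = TRUE) {
  if (anyNA(m)) stop("matrix must be fully observed (impute first)")
  a <- ann_for(ann, m)
  sel <- a$group %in% contrast
  v <- unclass(m)[, sel, drop = FALSE]
  grp <- a$group[sel]
  ord <- order(grp != contrast[1])      # group A columns first
  v <- v[, ord, drop = FALSE]
  nA <- sum(grp == contrast[1]); n <- ncol(v)
  if (nA < 2 || n - nA < 2) stop("need >= 2 samples per group")

  st <- row_group_t(v, seq_len(nA), seq(nA + 1, n))
  obs <- abs(st$t); obs[!is.finite(obs)] <- 0
  pm <- perm_abs_t(v, nA, n, n_perm, seed, balanced = balanced)
  null_vec <- as.vector(pm$abs_t)
  null_vec[!is.finite(null_vec)] <- 0
  null_abs <- sort(null_vec)

  n_null_ge <- length(null_abs) - findInterval(obs, null_abs, left.open = TRUE)
  sorted_obs <- sort(obs)
  n_obs_ge <- length(obs) - findInterval(obs, sorted_obs, left.open = TRUE)
  q <- (n_null_ge / pm$n_perm) / n_obs_ge
  # enforce q non-increasing in |t|: running minimum taken from the least
  # significant feature toward the largest statistic (the BH-style sweep)
  o <- order(obs, decreasing = TRUE)
  q[o] <- rev(cummin(rev(q[o])))
  q <- pmin(q, 1)
  names(q) <- rownames(m)
  q
}

#' Call regulated features from a differential result
#'
#' `up` iff `padj < padj_cut` and `log2fc >= lfc_cut`; `down` iff
#' `padj < padj_cut` and `log2fc <= -lfc_cut`; otherwise `none`. The column
#' used for significance can be switched to the permutation q-value.
#'
#' @param de data frame from [differential_stats()].
#' @param padj_cut adjusted-p (or q) cutoff, default 0.01.
#' @param lfc_cut absolute log2 fold-change cutoff, default 1.
#' @param sig_col column holding the significance value ("padj" or "q").
#' @return `de` with a `call` column (factor up/down/none).
#' @export
call_regulated <- function(de, padj_cut = 0.01, lfc_cut = 1, sig_col = "padj") {
  sig <- de[[sig_col]]
  if (anyNA(sig)) warning("missing ", sig_col, " for some features: called none")
  call <- rep("none", nrow(de))
  ok <- !is.na(sig) & sig < padj_cut
  call[ok & de$log2fc >= lfc_cut] <- "up"
  call[ok & de$log2fc <= -lfc_cut] <- "down"
  de$call <- factor(call, levels = c("up", "down", "none"))
  de
}

#' Differential-expression subscore
#'
#' The product `-log10(padj) * |log2fc|`: large for features that are both
#' significant and strongly changed, zero when padj = 1. `padj = 0` is
#' clamped to the smallest representable positive double with a warning.
#'
#' @param padj adjusted p-values in (0, 1].
#' @param log2fc log2 fold changes.
#' @return non-negative scores (NA propagated).
#' @export
dge_score <- function(padj, log2fc) {
  if (any(padj < 0 | padj > 1, na.rm = TRUE)) stop("padj must lie in [0, 1]")
  if (any(padj == 0, na.rm = TRUE)) {
    warning("padj of 0 clamped to the smallest positive double")
    padj[!is.na(padj) & padj == 0] <- .Machine$double.xmin
  }
  -log10(padj) * abs(log2fc)
}

#' Cluster z-scored time profiles
#'
#' Each feature's time course of log2 ratios is standardized (mean 0, sd 1
#' across time points) and clustered by agglomerative hierarchical clustering
#' with Euclidean distance and average linkage; the tree is cut into `k`
#' clusters. Constant profiles (sd 0) cannot be standardized and are
#' excluded, and reported. Profiles identical after standardization (affine
#' transforms of each other) always share a cluster; if fewer distinct
#' standardized profiles than `k` exist, fewer clusters are returned.
#'
#' @param log_ratios numeric matrix, features x time points, with rownames.
#' @param k number of clusters.
#' @return list: `assignment` (data frame feature_id, cluster), `excluded`
#'   (character vector), `hclust` (the tree).
#' @export
cluster_time_profiles <- function(log_ratios, k) {
  if (nrow(log_ratios) < k) stop("fewer features than clusters")
  if (ncol(log_ratios) < 2) stop("need >= 2 time points")
  log_ratios <- log_ratios[order(rownames(log_ratios)), , drop = FALSE]
  sds <- apply(log_ratios, 1, stats::sd)
  excluded <- rownames(log_ratios)[sds == 0]
  z <- log_ratios[sds > 0, , drop = FALSE]
  z <- t(scale(t(z)))
  # profiles identical after z-scoring (i.e. affine-equivalent inputs) are
  # clustered as one entity, so they can never be split across clusters
  key <- apply(round(z, 10), 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  zu <- z[uniq, , drop = FALSE]
  if (nrow(zu) == 1) {
    hc <- NULL
    clu <- 1L
  } else {
    hc <- stats::hclust(stats::dist(zu), method = "average")
    clu <- stats::cutree(hc, k = min(k, nrow(zu)))
  }
  cl <- unname(clu[match(key, key[uniq])])
  list(assignment = data.frame(feature_id = rownames(z), cluster = cl,
                               stringsAsFactors = FALSE),
       excluded = excluded, hclust = hc)
}

#' Fisher-exact overrepresentation analysis
#'
#' One-sided hypergeometric upper-tail test of each term's overlap with a
#' selected feature set against a background, with Benjamini-Hochberg
#' correction across terms. Term sets are intersected with the background
#' first. The enrichment factor is
#' `(overlap / selected size) / (term size / background size)`.
#'
#' @param selected character vector, subset of `background`.
#' @param background character vector of all eligible features.
#' @param term_sets named list of character vectors.
#' @return data frame: term, overlap, term_size, selected_size,
#'   background_size, enrichment, p, padj.
#' @export
fisher_ora <- function(selected, background, term_sets) {
  if (!length(selected)) stop("`selected` must be non-empty")
  if (length(setdiff(selected, background))) stop("`selected` must be a subset of `background`")
  bg <- length(unique(background))
  ns <- length(unique(selected))
  rows <- lapply(names(term_sets), function(tm) {
    ts <- intersect(term_sets[[tm]], background)
    ov <- length(intersect(selected, ts))
    nt <- length(ts)
    p <- if (nt == 0) 1 else stats::phyper(ov - 1, nt, bg - nt, ns, lower.tail = FALSE)
    ef <- if (nt == 0) NA_real_ else (ov / ns) / (nt / bg)
    data.frame(term = tm, overlap = ov, term_size = nt, selected_size = ns,
               background_size = bg, enrichment = ef, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  out
}
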