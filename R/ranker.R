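## Multi-dimensional weighted-sum biomarker ranking.
##
## Twelve subscores map onto four dimensions:
##   plasma specificity : plasma dge, plasma histo r2
##   liver specificity  : liver protein dge, liver RNA dge,
##                        liver protein histo r2, liver RNA histo r2
##   prior evidence     : fibrosis association, two literature subscores,
##                        patent flag, database flag
##   secreted class     : secreted flag
## Each dimension score lies in [0, 1]; the total is the weighted sum of the
## dimension scores under a weight setting whose weights sum to 1.

DIMENSION_MAP <- list(
  plasma = c("plasma_dge", "plasma_histo_r2"),
  liver = c("liver_protein_dge", "liver_rna_dge",
            "liver_protein_histo_r2", "liver_rna_histo_r2"),
  prior = c("fibrosis_association", "lit_pubs", "lit_pubs_vs_expected",
            "patent_flag", "database_flag"),
  secreted = "secreted_flag")

#' The six packaged weight settings
#'
#' Reads the packaged weight-setting file: default (0.3/0.3/0.2/0.2), prior
#' knowledge (0/0/1/0), balanced (0.2/0.2/0.4/0.2), liver/plasma specific
#' (0.5/0.5/0/0), liver specific (0/1/0/0), plasma specific (1/0/0/0);
#' columns are the four dimension weights (plasma, liver, prior, secreted).
#'
#' @return data frame with columns name, plasma, liver, prior, secreted.
#' @export
weight_settings <- function() {
  load_weight_settings(system.file("extdata", "weight_settings.json",
                                   package = "fibromark", mustWork = TRUE))
}

#' Load weight settings from a JSON or TSV file
#'
#' @param path file with fields/columns name, plasma, liver, prior, secreted.
#' @return validated data frame of weight settings.
#' @export
load_weight_settings <- function(path) {
  w <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path)
       else utils::read.delim(path, stringsAsFactors = FALSE)
  validate_weights(w)
  w
}

validate_weights <- function(w) {
  dims <- c("plasma", "liver", "prior", "secreted")
  stopifnot(all(c("name", dims) %in% names(w)))
  if (anyDuplicated(w$name)) stop("duplicate weight-setting names")
  vals <- as.matrix(w[dims])
  if (any(vals < 0 | vals > 1)) stop("weights must lie in [0, 1]")
  if (any(abs(rowSums(vals) - 1) > 1e-9)) stop("each setting's weights must sum to 1")
  invisible(w)
}

#' Rank-normalize a vector to [0, 1]
#'
#' Average ranks for ties, then `(rank - 1) / (n - 1)`: the minimum maps to
#' 0, the maximum to 1; a single value maps to 0.5. NA values stay NA and do
#' not consume ranks.
#'
#' @param values numeric vector with at least one finite value.
#' @return numeric vector in [0, 1].
#' @export
rank_normalize <- function(values) {
  ok <- !is.na(values)
  if (!any(ok)) stop("all values missing")
  n <- sum(ok)
  out <- rep(NA_real_, length(values))
  out[ok] <- if (n == 1) 0.5 else (rank(values[ok], ties.method = "average") - 1) / (n - 1)
  out
}

#' Literature-evidence subscores
#'
#' Two subscores per candidate, each rank-normalized over the candidate
#' cohort: (A) the raw publication count, (B) the count divided by its
#' expected count (observed-vs-expected enrichment).
#'
#' @param pub_count non-negative publication counts.
#' @param expected positive expected counts.
#' @return data frame with columns `lit_pubs` and `lit_pubs_vs_expected`,
#'   both in [0, 1].
#' @export
literature_subscore <- function(pub_count, expected) {
  if (any(pub_count < 0, na.rm = TRUE)) stop("publication counts must be >= 0")
  if (any(expected <= 0, na.rm = TRUE)) stop("expected counts must be > 0")
  data.frame(lit_pubs = rank_normalize(pub_count),
             lit_pubs_vs_expected = rank_normalize(pub_count / expected))
}

#' Assemble the per-candidate subscore table
#'
#' The candidate set is the rat proteins that (a) have a human ortholog in
#' the id map and (b) were detected — i.e. survived preprocessing — in both
#' the liver and the plasma protein matrices. For each candidate the twelve
#' subscores are computed: differential-expression subscores via
#' [dge_score()] per contrast, rank-normalized over the candidate cohort;
#' histology-correlation subscores as raw r-squared; the fibrosis-association
#' score raw; two literature subscores via [literature_subscore()]; and the
#' three binary flags. Missing prior evidence counts as 0 (absence of
#' evidence), as do missing correlation or differential entries.
#'
#' @param de named list of [differential_stats()] tables:
#'   `plasma_protein` and `liver_protein` keyed by rat protein id,
#'   `liver_rna` keyed by rat gene id.
#' @param corr named list of [histology_correlation()] tables with the same
#'   names and keying.
#' @param prior prior-evidence table keyed by `gene_id` (rat gene id).
#' @param idmap id-mapping table (rat_protein_id, rat_gene_id,
#'   human_ortholog, secreted).
#' @return data frame (class `subscore_table`): gene_id, rat_protein_id and
#'   the 12 subscores, each in [0, 1].
#' @export
assemble_subscores <- function(de, corr, prior, idmap) {
  need <- c("plasma_protein", "liver_protein", "liver_rna")
  stopifnot(all(need %in% names(de)), all(need %in% names(corr)))
  cand <- idmap[!is.na(idmap$human_ortholog) &
                  idmap$rat_protein_id %in% de$liver_protein$feature_id &
                  idmap$rat_protein_id %in% de$plasma_protein$feature_id, , drop = FALSE]
  if (!nrow(cand)) stop("empty candidate set")

  pull <- function(tab, key, col) {
    x <- tab[[col]][match(key, tab$feature_id)]
    ifelse(is.na(x), 0, x)
  }
  dge_sub <- function(tab, key) {
    padj <- tab$padj[match(key, tab$feature_id)]
    lfc <- tab$log2fc[match(key, tab$feature_id)]
    s <- dge_score(pmax(padj, .Machine$double.xmin), lfc)
    rank_normalize(ifelse(is.na(s), 0, s))
  }
  pid <- cand$rat_protein_id; gid <- cand$rat_gene_id
  pri <- prior[match(gid, prior$gene_id), , drop = FALSE]
  lit <- literature_subscore(ifelse(is.na(pri$pub_count), 0, pri$pub_count),
                             ifelse(is.na(pri$expected_count), 1, pri$expected_count))
  out <- data.frame(
    gene_id = gid, rat_protein_id = pid,
    plasma_dge = dge_sub(de$plasma_protein, pid),
    plasma_histo_r2 = pull(corr$plasma_protein, pid, "r2"),
    liver_protein_dge = dge_sub(de$liver_protein, pid),
    liver_rna_dge = dge_sub(de$liver_rna, gid),
    liver_protein_histo_r2 = pull(corr$liver_protein, pid, "r2"),
    liver_rna_histo_r2 = pull(corr$liver_rna, gid, "r2"),
    fibrosis_association = ifelse(is.na(pri$fibrosis_association), 0, pri$fibrosis_association),
    lit_pubs = lit$lit_pubs,
    lit_pubs_vs_expected = lit$lit_pubs_vs_expected,
    patent_flag = ifelse(is.na(pri$patent_flag), 0, pri$patent_flag),
    database_flag = ifelse(is.na(pri$database_flag), 0, pri$database_flag),
    secreted_flag = cand$secreted,
    stringsAsFactors = FALSE)
  class(out) <- c("subscore_table", "data.frame")
  out
}

#' Aggregate subscores into the four dimension scores
#'
#' Each dimension score is the mean of its mapped subscores (equal weights
#' within a dimension), so all four lie in [0, 1] and are commensurable under
#' the weight settings. `raw_sum = TRUE` reproduces a literal sum-of-subscores
#' reading instead (dimensions then live on different scales).
#'
#' @param subscores a table from [assemble_subscores()].
#' @param raw_sum sum instead of mean within each dimension.
#' @return data frame: gene_id plus columns plasma, liver, prior, secreted.
#' @export
dimension_scores <- function(subscores, raw_sum = FALSE) {
  agg <- function(cols) {
    v <- as.matrix(subscores[cols])
    if (raw_sum) rowSums(v) else rowMeans(v)
  }
  data.frame(gene_id = subscores$gene_id,
             plasma = agg(DIMENSION_MAP$plasma),
             liver = agg(DIMENSION_MAP$liver),
             prior = agg(DIMENSION_MAP$prior),
             secreted = agg(DIMENSION_MAP$secreted),
             stringsAsFactors = FALSE)
}

#' Total biomarker score and ranking under one weight setting
#'
#' The total score is the weighted sum of the four dimension scores; ranking
#' is by descending total, ties broken lexicographically by gene id (stable,
#' 1 = best). Per-dimension contributions `w_j * dim_j` are recorded for
#' stacked-contribution displays.
#'
#' @param dims data frame from [dimension_scores()].
#' @param setting one row of a weight-setting table (name + four weights).
#' @return data frame ordered by rank: gene_id, dimension scores,
#'   contributions (`contrib_*`), total, rank, setting.
#' @export
total_score_and_rank <- function(dims, setting) {
  validate_weights(as.data.frame(setting))
  w <- unlist(setting[c("plasma", "liver", "prior", "secreted")])
  contrib <- sweep(as.matrix(dims[names(w)]), 2, w, "*")
  colnames(contrib) <- paste0("contrib_", names(w))
  total <- rowSums(contrib)
  out <- cbind(dims, contrib,
               data.frame(total = total, setting = setting$name,
                          stringsAsFactors = FALSE))
  out <- out[order(-out$total, out$gene_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Sensitivity analysis over weight settings
#'
#' Ranks every candidate under each weight setting, collects the total-score
#' matrix (candidates x settings), each candidate's best (minimum) rank
#' across settings, and a candidate ordering from hierarchical clustering
#' (Euclidean distance, average linkage) of the per-candidate score vectors.
#'
#' @param dims data frame from [dimension_scores()].
#' @param settings weight-setting table with >= 2 rows (default: the six
#'   packaged settings).
#' @return list: `scores` (matrix), `ranks` (matrix), `best_rank` (named
#'   vector), `order` (gene ids in clustering order), `rankings` (list of
#'   per-setting tables).
#' @export
sensitivity_analysis <- function(dims, settings = weight_settings()) {
  validate_weights(settings)
  if (nrow(settings) < 2) stop("need >= 2 weight settings")
  rankings <- lapply(seq_len(nrow(settings)), function(i)
    total_score_and_rank(dims, settings[i, , drop = FALSE]))
  names(rankings) <- settings$name
  ids <- sort(dims$gene_id)
  scores <- sapply(rankings, function(r) r$total[match(ids, r$gene_id)])
  ranks <- sapply(rankings, function(r) r$rank[match(ids, r$gene_id)])
  rownames(scores) <- rownames(ranks) <- ids
  best <- apply(ranks, 1, min)
  ord <- if (length(ids) > 2) {
    hc <- stats::hclust(stats::dist(scores), method = "average")
    ids[hc$order]
  } else ids
  list(scores = scores, ranks = ranks, best_rank = best, order = ord,
       rankings = rankings)
}
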