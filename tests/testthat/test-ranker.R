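test_that("rank normalization maps to [0,1] with average ties", {
  expect_equal(rank_normalize(c(10, 20, 30)), c(0, 0.5, 1))
  expect_equal(rank_normalize(c(5, 5)), c(0.5, 0.5))
  expect_equal(rank_normalize(7), 0.5)
  expect_error(rank_normalize(c(NA, NA)), "all values missing")
  expect_equal(rank_normalize(c(3, NA, 1)), c(1, NA, 0))
  set.seed(8)
  x <- rnorm(100)
  expect_equal(cor(rank_normalize(x), x, method = "spearman"), 1)
})

test_that("literature subscores rank counts and observed/expected ratios", {
  all0 <- literature_subscore(c(0, 0, 0), c(1, 2, 3))
  expect_equal(all0$lit_pubs, rep(0.5, 3))
  l <- literature_subscore(c(0, 10, 100), rep(1, 3))
  expect_equal(l$lit_pubs, c(0, 0.5, 1))
  r <- literature_subscore(c(10, 10), c(1, 100))
  expect_equal(r$lit_pubs, c(0.5, 0.5))
  expect_equal(r$lit_pubs_vs_expected, c(1, 0))
  expect_error(literature_subscore(c(-1, 2), c(1, 1)), ">= 0")
  expect_error(literature_subscore(c(1, 2), c(0, 1)), "> 0")
})

test_that("the six packaged weight settings are valid and exact", {
  w <- weight_settings()
  expect_equal(nrow(w), 6)
  dims <- c("plasma", "liver", "prior", "secreted")
  expect_equal(unname(rowSums(w[dims])), rep(1, 6))
  expect_equal(unlist(w[w$name == "default", dims], use.names = FALSE),
               c(0.3, 0.3, 0.2, 0.2))
  expect_equal(unlist(w[w$name == "prior_knowledge", dims], use.names = FALSE),
               c(0, 0, 1, 0))
  bad <- w; bad$plasma[1] <- 0.5
  expect_error(sensitivity_analysis(data.frame(), bad), "sum to 1")
  dupw <- w; dupw$name[2] <- dupw$name[1]
  expect_error(sensitivity_analysis(data.frame(), dupw), "duplicate")
})

test_that("dimension scores are means of mapped subscores, in [0,1]", {
  sub <- data.frame(gene_id = c("a", "b", "c"),
                    plasma_dge = c(1, 0, 0.2), plasma_histo_r2 = c(1, 0, 0.8),
                    liver_protein_dge = c(1, 0, 0.4), liver_rna_dge = c(1, 0, 0.4),
                    liver_protein_histo_r2 = c(1, 0, 0.4),
                    liver_rna_histo_r2 = c(1, 0, 0.4),
                    fibrosis_association = c(1, 0, 0.5), lit_pubs = c(1, 0, 0.5),
                    lit_pubs_vs_expected = c(1, 0, 0.5), patent_flag = c(1, 0, 0),
                    database_flag = c(1, 0, 1), secreted_flag = c(1, 0, 1))
  d <- dimension_scores(sub)
  expect_equal(unlist(d[1, -1], use.names = FALSE), rep(1, 4))
  expect_equal(unlist(d[2, -1], use.names = FALSE), rep(0, 4))
  expect_equal(d$plasma[3], 0.5)
  expect_equal(d$liver[3], 0.4)
  raw <- dimension_scores(sub, raw_sum = TRUE)
  expect_equal(raw$liver[1], 4)
  expect_equal(raw$prior[1], 5)
})

test_that("total score and ranks equal the brute-force oracle", {
  set.seed(13)
  n <- 50
  dims <- data.frame(gene_id = sprintf("g%02d", sample(n)),
                     plasma = runif(n), liver = runif(n),
                     prior = runif(n), secreted = runif(n))
  setting <- weight_settings()[1, ]
  out <- total_score_and_rank(dims, setting)
  # oracle: explicit per-candidate dot product and argsort
  w <- c(0.3, 0.3, 0.2, 0.2)
  tot <- sapply(seq_len(n), function(i)
    sum(w * unlist(dims[i, c("plasma", "liver", "prior", "secreted")])))
  ord <- order(-tot, dims$gene_id)
  expect_equal(out$gene_id, dims$gene_id[ord])
  expect_equal(out$total, tot[ord])
  expect_equal(out$rank, seq_len(n))
  expect_equal(out$total,
               out$contrib_plasma + out$contrib_liver + out$contrib_prior +
                 out$contrib_secreted)
  # perfect candidate under the default weights scores exactly 1
  one <- total_score_and_rank(data.frame(gene_id = "a", plasma = 1, liver = 1,
                                         prior = 1, secreted = 1), setting)
  expect_equal(one$total, 1)
  # unit-vector weights reduce to the single-dimension ranking
  proj <- total_score_and_rank(dims, data.frame(name = "p", plasma = 0, liver = 0,
                                                prior = 1, secreted = 0))
  expect_equal(proj$gene_id, dims$gene_id[order(-dims$prior, dims$gene_id)])
})

test_that("subscore assembly enforces the candidate filter and [0,1] ranges", {
  st <- small_study(seed = 19, missing_rate = 0)
  prior <- generate_prior_evidence(st$truth$feature_id, st$truth, seed = 2)
  ann <- st$annotation
  prep <- function(m) center_batches(log2_transform(normalize_total_and_scale(m)), ann)
  lp <- prep(st$liver_protein); pp <- prep(st$plasma_protein)
  cpm <- cpm_and_expressed_filter(st$liver_rna, ann)
  rna <- omics_matrix(log2(unclass(cpm$cpm) + 1), "log2")
  wk12 <- ann$sample_id[ann$week == 12]
  rna12 <- omics_matrix(unclass(rna)[, wk12], "log2")
  de <- list(liver_protein = call_regulated(differential_stats(lp, ann, c("CSAA", "CDAA"))),
             plasma_protein = call_regulated(differential_stats(pp, ann, c("CSAA", "CDAA"))),
             liver_rna = call_regulated(differential_stats(rna12, ann, c("CSAA", "CDAA"))))
  corr <- list(liver_protein = histology_correlation(lp, ann),
               plasma_protein = histology_correlation(pp, ann),
               liver_rna = histology_correlation(rna, ann))
  sub <- assemble_subscores(de, corr, prior, st$id_map)

  # candidates: human ortholog AND detected in liver + plasma protein data
  expected <- st$id_map$rat_gene_id[!is.na(st$id_map$human_ortholog) &
                                      st$id_map$rat_protein_id %in% rownames(pp) &
                                      st$id_map$rat_protein_id %in% rownames(lp)]
  expect_setequal(sub$gene_id, expected)
  no_orth <- st$id_map$rat_gene_id[is.na(st$id_map$human_ortholog)]
  expect_false(any(no_orth %in% sub$gene_id))
  liver_only <- setdiff(sub$gene_id, sub$gene_id[sub$rat_protein_id %in% rownames(pp)])
  expect_length(liver_only, 0)
  score_cols <- setdiff(names(sub), c("gene_id", "rat_protein_id"))
  expect_length(score_cols, 12)
  for (cn in score_cols) {
    expect_true(all(sub[[cn]] >= 0 & sub[[cn]] <= 1), info = cn)
  }
})

test_that("raising one subscore never lowers the total under non-negative weights", {
  set.seed(23)
  sub_cols <- unlist(fibromark:::DIMENSION_MAP)
  n <- 20
  sub <- data.frame(gene_id = sprintf("g%02d", 1:n))
  for (cn in sub_cols) sub[[cn]] <- runif(n)
  w <- weight_settings()
  for (i in seq_len(nrow(w))) {
    base <- total_score_and_rank(dimension_scores(sub), w[i, ])
    for (cn in sample(sub_cols, 4)) {
      bumped <- sub
      j <- sample(n, 1)
      bumped[[cn]][j] <- min(1, bumped[[cn]][j] + 0.3)
      tot2 <- total_score_and_rank(dimension_scores(bumped), w[i, ])
      id <- sub$gene_id[j]
      expect_gte(tot2$total[tot2$gene_id == id], base$total[base$gene_id == id])
    }
  }
})

test_that("sensitivity analysis reports scores, best ranks and an ordering", {
  set.seed(31)
  n <- 15
  dims <- data.frame(gene_id = sprintf("g%02d", 1:n), plasma = runif(n),
                     liver = runif(n), prior = runif(n), secreted = rbinom(n, 1, 0.3))
  sens <- sensitivity_analysis(dims)
  expect_equal(dim(sens$scores), c(n, 6))
  expect_equal(unname(sens$best_rank), unname(apply(sens$ranks, 1, min)))
  expect_setequal(sens$order, dims$gene_id)
  # every per-setting rank column is a permutation of 1..n
  for (j in seq_len(ncol(sens$ranks))) expect_setequal(sens$ranks[, j], 1:n)
  # a candidate dominating everywhere has best rank 1 in every setting
  dims2 <- dims; dims2[1, -1] <- c(1, 1, 1, 1)
  sens2 <- sensitivity_analysis(dims2)
  expect_equal(unname(sens2$ranks["g01", ]), rep(1L, 6), ignore_attr = TRUE)
  expect_equal(unname(sens2$best_rank["g01"]), 1L, ignore_attr = TRUE)
})

test_that("top candidate under the null is uniform across seeds", {
  # zero effects, evidence decoupled, deterministic candidate set
  tops <- vapply(1:200, function(s) {
    st <- generate_study(
      study_design(animals_per_group = 4, weeks = 12, seed = s),
      effect_config(n_rna = 30, n_liver_protein = 25, n_plasma_protein = 20,
                    fraction_de = 0, fraction_secreted_biomarker = 0,
                    fraction_antiregulated = 0, effect_size_log2 = 0,
                    missing_rate = 0, ortholog_rate = 1))
    prior <- generate_prior_evidence(st$truth$feature_id, NULL, seed = s + 1000,
                                     evidence_fraction = 0)
    ann <- st$annotation
    prep <- function(m) center_batches(log2_transform(normalize_total_and_scale(m)), ann)
    lp <- prep(st$liver_protein); pp <- prep(st$plasma_protein)
    rna <- omics_matrix(log2(unclass(cpm_and_expressed_filter(st$liver_rna, ann)$cpm) + 1), "log2")
    de <- list(liver_protein = differential_stats(lp, ann, c("CSAA", "CDAA")),
               plasma_protein = differential_stats(pp, ann, c("CSAA", "CDAA")),
               liver_rna = differential_stats(rna, ann, c("CSAA", "CDAA")))
    corr <- list(liver_protein = histology_correlation(lp, ann),
                 plasma_protein = histology_correlation(pp, ann),
                 liver_rna = histology_correlation(rna, ann))
    sub <- assemble_subscores(de, corr, prior, st$id_map)
    rk <- total_score_and_rank(dimension_scores(sub), weight_settings()[1, ])
    rk$gene_id[1]
  }, character(1))
  obs <- table(factor(tops, levels = sprintf("g%05d", 1:20)))
  gof <- chisq.test(obs, p = rep(1 / 20, 20))
  expect_gt(gof$p.value, 0.01)
})
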