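#' Pipeline configuration
#'
#' Collects every stage's parameters with the study defaults: two diet groups
#' of eight animals at weeks 4/8/12, proteomics in two batches at week 12,
#' presence filter at 6-of-8, downshifted imputation (liver 2.5/0.2, plasma
#' 1.8/0.3), DE cutoffs padj < 0.01 and |log2FC| >= 1, permutation FDR, and
#' the six packaged weight settings. A single global seed deterministically
#' derives per-stage seeds, so stages can be rerun in isolation.
#'
#' @param seed global integer seed.
#' @param design list of [study_design()] arguments (less `seed`).
#' @param effects list of [effect_config()] arguments.
#' @param evidence_fraction passed to [generate_prior_evidence()].
#' @param prep list: min_present, target_mean, liver_downshift, liver_width,
#'   plasma_downshift, plasma_width, cpm_threshold.
#' @param de list: padj_cut, lfc_cut, n_perm.
#' @param weights weight-setting table (default: packaged six).
#' @param top_n candidates carried into the PC-regression validation.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            design = list(),
                            effects = list(),
                            evidence_fraction = 0.8,
                            prep = list(),
                            de = list(),
                            weights = NULL,
                            top_n = 10) {
  prep_def <- list(min_present = 6, target_mean = 100,
                   liver_downshift = 2.5, liver_width = 0.2,
                   plasma_downshift = 1.8, plasma_width = 0.3,
                   cpm_threshold = 1)
  de_def <- list(padj_cut = 0.01, lfc_cut = 1, n_perm = 1000)
  cfg <- list(seed = as.integer(seed), design = design, effects = effects,
              evidence_fraction = evidence_fraction,
              prep = utils::modifyList(prep_def, prep),
              de = utils::modifyList(de_def, de),
              weights = if (is.null(weights)) weight_settings() else validate_weights(weights),
              top_n = top_n)
  stopifnot(cfg$de$padj_cut > 0, cfg$de$padj_cut <= 1, cfg$de$lfc_cut >= 0,
            cfg$prep$min_present >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' @param path JSON file whose top-level fields match the arguments of
#'   [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  do.call(pipeline_config, raw[intersect(names(raw), names(formals(pipeline_config)))])
}

# preprocess one proteomics matrix: presence filter -> total normalization ->
# log2 -> downshifted imputation -> batch centering
prep_protein <- function(m, ann, prep, downshift, width, seed) {
  m <- filter_by_group_presence(m, ann, prep$min_present)
  m <- normalize_total_and_scale(m, prep$target_mean)
  m <- log2_transform(m)
  m <- impute_downshifted(m, downshift, width, seed = seed)
  center_batches(m, ann)
}

#' Run the full discovery pipeline
#'
#' simulate -> preprocess -> differential statistics -> fibrosis correlation
#' -> subscore assembly -> weighted ranking + sensitivity analysis ->
#' PC-regression validation. Every stage records its parameters and derived
#' seed in a manifest; identical config and seed reproduce identical tables.
#' If `out_dir` is given all stage outputs are written as TSV plus a
#' `manifest.json` (with md5 checksums); a failed stage aborts with the
#' stage named, retaining earlier outputs.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list of stage results: study, processed, de, corr, concordance,
#'   subscores, dims, rankings, sensitivity, validation, recovery, manifest.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  manifest <- list(package = "fibromark",
                   version = as.character(utils::packageVersion("fibromark")),
                   seed = cfg$seed, stages = list())
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  stage <- function(name, params, fn) {
    sseed <- derive_seed(cfg$seed, name)
    out <- tryCatch(fn(sseed),
                    error = function(e) stop("pipeline stage `", name, "` failed: ",
                                             conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- list(params = params, seed = sseed)
    out
  }

  ## -- simulate --
  res$study <- stage("simulate", cfg$design, function(s) {
    design <- do.call(study_design, c(cfg$design, list(seed = s)))
    effects <- do.call(effect_config, cfg$effects)
    study <- generate_study(design, effects)
    study$prior <- generate_prior_evidence(study$truth$feature_id, study$truth,
                                           seed = derive_seed(s, "evidence"),
                                           evidence_fraction = cfg$evidence_fraction)
    study
  })
  study <- res$study
  ann <- study$annotation

  ## -- prep --
  res$processed <- stage("prep", cfg$prep, function(s) {
    liver <- prep_protein(study$liver_protein, ann, cfg$prep,
                          cfg$prep$liver_downshift, cfg$prep$liver_width,
                          derive_seed(s, "liver"))
    plasma <- prep_protein(study$plasma_protein, ann, cfg$prep,
                           cfg$prep$plasma_downshift, cfg$prep$plasma_width,
                           derive_seed(s, "plasma"))
    cpmres <- cpm_and_expressed_filter(study$liver_rna, ann, cfg$prep$cpm_threshold)
    cpm_expr <- unclass(cpmres$cpm)[cpmres$expressed, , drop = FALSE]
    rna_log2 <- omics_matrix(log2(cpm_expr + 1), scale = "log2")
    list(liver_protein = liver, plasma_protein = plasma,
         rna_cpm = cpmres$cpm, rna_log2 = rna_log2, expressed = cpmres$expressed)
  })
  pr <- res$processed
  wk12 <- ann$sample_id[ann$week == max(ann$week)]
  rna12 <- omics_matrix(unclass(pr$rna_log2)[, intersect(wk12, colnames(pr$rna_log2)), drop = FALSE],
                        scale = "log2")
  contrast <- unname(study$design$groups[c("control", "diseased")])

  ## -- diffexp --
  res$de <- stage("diffexp", cfg$de, function(s) {
    de <- list(
      liver_protein = differential_stats(pr$liver_protein, ann, contrast, "liver_protein"),
      plasma_protein = differential_stats(pr$plasma_protein, ann, contrast, "plasma_protein"),
      liver_rna = differential_stats(rna12, ann, contrast, "liver_rna"))
    de$liver_protein$q <- permutation_fdr(pr$liver_protein, ann, contrast,
                                          cfg$de$n_perm, derive_seed(s, "liver"))
    de$plasma_protein$q <- permutation_fdr(pr$plasma_protein, ann, contrast,
                                           cfg$de$n_perm, derive_seed(s, "plasma"))
    de$liver_protein <- call_regulated(de$liver_protein, cfg$de$padj_cut, cfg$de$lfc_cut, "q")
    de$plasma_protein <- call_regulated(de$plasma_protein, cfg$de$padj_cut, cfg$de$lfc_cut, "q")
    de$liver_rna <- call_regulated(de$liver_rna, cfg$de$padj_cut, cfg$de$lfc_cut, "padj")
    de
  })

  ## -- correlate --
  res$corr <- stage("correlate", list(), function(s) list(
    liver_protein = histology_correlation(pr$liver_protein, ann),
    plasma_protein = histology_correlation(pr$plasma_protein, ann),
    liver_rna = histology_correlation(pr$rna_log2, ann)))
  res$concordance <- stage("concordance", list(), function(s) {
    dep <- res$de$liver_protein
    dep$feature_id <- study$id_map$rat_gene_id[match(dep$feature_id, study$id_map$rat_protein_id)]
    concordance_classes(res$de$liver_rna, dep)
  })

  ## -- rank --
  res$subscores <- stage("rank", list(settings = cfg$weights$name), function(s)
    assemble_subscores(res$de, res$corr, study$prior, study$id_map))
  res$dims <- dimension_scores(res$subscores)
  res$sensitivity <- sensitivity_analysis(res$dims, cfg$weights)
  res$rankings <- res$sensitivity$rankings

  ## -- evaluate --
  res$validation <- stage("evaluate", list(top_n = cfg$top_n), function(s) {
    pca <- list(liver_rna = pca_scores(rna12, k = 3),
                liver_protein = pca_scores(pr$liver_protein, k = 3))
    top <- utils::head(res$rankings$default, cfg$top_n)
    plasma_v <- unclass(pr$plasma_protein)
    regs <- lapply(seq_len(nrow(top)), function(i) {
      pid <- res$subscores$rat_protein_id[match(top$gene_id[i], res$subscores$gene_id)]
      x <- plasma_v[pid, ]
      do.call(rbind, lapply(names(pca), function(kind) {
        r <- marker_pc_regression(x, pca[[kind]])
        cbind(data.frame(gene_id = top$gene_id[i], matrix = kind), r)
      }))
    })
    list(pca = pca, regression = do.call(rbind, regs))
  })

  ## -- recovery vs ground truth --
  truth_bio <- study$truth$feature_id[study$truth$class == "secreted_biomarker"]
  top20 <- utils::head(res$rankings$default$gene_id, 20)
  res$recovery <- list(
    n_planted = length(truth_bio),
    in_top20 = sum(truth_bio %in% top20),
    fraction = if (length(truth_bio)) mean(truth_bio %in% top20) else NA_real_)
  manifest$recovery <- res$recovery

  if (!is.null(out_dir)) {
    write_study(study, file.path(out_dir, "study"))
    write_table_tsv(study$prior, file.path(out_dir, "study", "prior_evidence.tsv"))
    write_omics_tsv(pr$liver_protein, file.path(out_dir, "liver_protein_processed.tsv"))
    write_omics_tsv(pr$plasma_protein, file.path(out_dir, "plasma_protein_processed.tsv"))
    for (k in names(res$de))
      write_table_tsv(res$de[[k]], file.path(out_dir, paste0("de_", k, ".tsv")))
    for (k in names(res$corr))
      write_table_tsv(res$corr[[k]], file.path(out_dir, paste0("histocorr_", k, ".tsv")))
    write_table_tsv(res$concordance$table, file.path(out_dir, "concordance.tsv"))
    write_table_tsv(as.data.frame(res$subscores), file.path(out_dir, "subscores.tsv"))
    for (k in names(res$rankings))
      write_table_tsv(res$rankings[[k]], file.path(out_dir, paste0("ranking_", k, ".tsv")))
    sens <- data.frame(gene_id = rownames(res$sensitivity$scores),
                       res$sensitivity$scores,
                       best_rank = res$sensitivity$best_rank, check.names = FALSE)
    write_table_tsv(sens, file.path(out_dir, "sensitivity_scores.tsv"))
    write_table_tsv(res$validation$regression, file.path(out_dir, "marker_pc_regression.tsv"))
    files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    files <- setdiff(files, file.path(out_dir, "manifest.json"))
    manifest$files <- lapply(stats::setNames(files, sub(paste0(out_dir, "/"), "", files)),
                             function(f) unname(tools::md5sum(f)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res$manifest <- manifest
  res
}
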