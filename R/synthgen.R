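#' Synthetic multi-omics study generator
#'
#' Emulates the structure of a preclinical diet-induced NASH study in rats:
#' a control (choline-supplemented, CSAA) and a diseased (choline-deficient,
#' CDAA) arm of `animals_per_group` animals per time point, liver RNA-Seq at
#' every week, and TMT-style liver and plasma proteomics at the final week
#' split over `batches` multiplexing runs. Disease severity is a latent
#' per-animal variable: zero (plus noise) in controls, increasing with week in
#' the diseased arm; the ordinal histology fibrosis score and all planted
#' expression effects derive from it, so ground truth is known for every
#' feature.
#'
#' @param groups named character vector `c(control = ..., diseased = ...)`.
#' @param animals_per_group animals per group per time point (>= 3).
#' @param weeks time points; proteomics is generated at `max(weeks)` only.
#' @param batches number of proteomics batches (runs).
#' @param seed integer; fully determines every random draw.
#' @return a `study_design` list.
#' @export
study_design <- function(groups = c(control = "CSAA", diseased = "CDAA"),
                         animals_per_group = 8,
                         weeks = c(4, 8, 12),
                         batches = 2,
                         seed = 1L) {
  stopifnot(length(groups) == 2, all(c("control", "diseased") %in% names(groups)))
  if (animals_per_group < 3) stop("animals_per_group must be >= 3")
  if (batches < 1) stop("at least one batch required")
  structure(list(groups = groups, animals_per_group = animals_per_group,
                 weeks = sort(weeks), batches = as.integer(batches),
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Effect configuration for the synthetic study
#'
#' Controls how many features each matrix has, which fractions of genes carry
#' planted effects, and the noise/coupling/censoring parameters. Feature
#' classes partition the gene set: `null` (no effect anywhere),
#' `liver_de_only` (RNA + coupled liver protein effect, plasma decoupled),
#' `secreted_biomarker` (liver effect propagated to plasma, attenuated),
#' `antiregulated` (liver protein effect sign flipped vs RNA).
#'
#' @param n_rna,n_liver_protein,n_plasma_protein feature counts per matrix;
#'   proteins map to the first genes, plasma proteins to the first liver
#'   proteins, so every plasma feature is also measured in liver and RNA.
#' @param fraction_de,fraction_secreted_biomarker,fraction_antiregulated
#'   gene fractions per non-null class (of `n_rna`); the rest are null.
#' @param effect_size_log2 central planted log2 fold change at full severity;
#'   per-feature magnitudes are uniform in 0.5x-2x this value, random sign.
#' @param rna_protein_coupling target feature-level Pearson correlation
#'   between RNA and liver-protein log2 effects, in [0, 1].
#' @param plasma_attenuation multiplier on the liver-protein effect for
#'   secreted biomarkers in plasma, in [0, 1].
#' @param missing_rate approximate overall left-censored missingness rate in
#'   the protein matrices.
#' @param censoring_steepness slope of the logistic censoring probability in
#'   log2-intensity units.
#' @param fibrosis_noise_sd noise added before rounding the fibrosis score.
#' @param severity_noise_sd per-animal spread of latent severity.
#' @param rna_base_log2,protein_base_log2,plasma_base_log2 mean baseline
#'   abundances (log2).
#' @param protein_noise_sd,plasma_noise_sd per-sample residual sd (log2).
#' @param batch_sd sd of per-feature batch offsets (log2).
#' @param nb_size negative-binomial size (inverse dispersion) for RNA counts.
#' @param secreted_background_rate fraction of non-biomarker proteins
#'   annotated secreted in the id map.
#' @param ortholog_rate fraction of rat proteins with a human ortholog.
#' @return an `effect_config` list.
#' @export
effect_config <- function(n_rna = 2000, n_liver_protein = 800, n_plasma_protein = 300,
                          fraction_de = 0.15,
                          fraction_secreted_biomarker = 0.005,
                          fraction_antiregulated = 0.01,
                          effect_size_log2 = 2,
                          rna_protein_coupling = 0.75,
                          plasma_attenuation = 0.8,
                          missing_rate = 0.05,
                          censoring_steepness = 2,
                          fibrosis_noise_sd = 0.3,
                          severity_noise_sd = 0.3,
                          rna_base_log2 = 8, protein_base_log2 = 10,
                          plasma_base_log2 = 10,
                          protein_noise_sd = 0.3, plasma_noise_sd = 0.3,
                          batch_sd = 0.3, nb_size = 50,
                          secreted_background_rate = 0.15,
                          ortholog_rate = 0.95) {
  fr <- c(fraction_de, fraction_secreted_biomarker, fraction_antiregulated)
  if (any(fr < 0) || sum(fr) > 1) stop("class fractions must be >= 0 and sum to <= 1")
  if (rna_protein_coupling < 0 || rna_protein_coupling > 1)
    stop("rna_protein_coupling must be in [0, 1]")
  if (plasma_attenuation < 0 || plasma_attenuation > 1)
    stop("plasma_attenuation must be in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (effect_size_log2 < 0) stop("effect_size_log2 must be >= 0")
  if (n_plasma_protein > n_liver_protein || n_liver_protein > n_rna)
    stop("need n_plasma_protein <= n_liver_protein <= n_rna")
  if (min(n_rna, n_liver_protein, n_plasma_protein) < 1) stop("feature counts must be positive")
  cfg <- as.list(environment())
  cfg$fr <- NULL
  structure(cfg, class = "effect_config")
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit sub-seed from a base seed and a stage label.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Map latent severity to an ordinal fibrosis score
#'
#' Applies an affine map, adds Gaussian noise, rounds and clips to the
#' ordinal histology staging range (default 0-4).
#'
#' @param severity numeric vector of latent per-animal severities.
#' @param noise_sd non-negative noise sd added before rounding.
#' @param seed integer seed.
#' @param intercept,slope affine map applied to severity (default identity).
#' @param max_score top of the ordinal scale.
#' @return integer scores in `[0, max_score]`.
#' @export
fibrosis_from_severity <- function(severity, noise_sd = 0, seed = 1L,
                                   intercept = 0, slope = 1, max_score = 4L) {
  if (any(!is.finite(severity))) stop("severity must be finite")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  with_seed(seed, {
    raw <- intercept + slope * severity + stats::rnorm(length(severity), 0, noise_sd)
    as.integer(pmin(pmax(round(raw), 0), max_score))
  })
}

#' Generate a complete synthetic multi-omics study
#'
#' See [study_design()] and [effect_config()] for the stated world. RNA is
#' simulated as negative-binomial counts with log2 mean linear in severity;
#' liver protein log2 intensity tracks severity through a per-feature effect
#' correlated with the RNA effect at `rna_protein_coupling` (sign-flipped for
#' the antiregulated class); plasma intensity of secreted biomarkers carries
#' `plasma_attenuation` times the liver-protein effect, all other plasma
#' features are decoupled from disease. Left-censored missingness and batch
#' offsets are injected into the protein matrices only.
#'
#' @param design a [study_design()].
#' @param effects an [effect_config()].
#' @return a `synthetic_study` list: `liver_rna` (counts), `liver_protein`,
#'   `plasma_protein` (linear intensities), `annotation`, `id_map`, `truth`.
#' @export
generate_study <- function(design = study_design(), effects = effect_config()) {
  stopifnot(inherits(design, "study_design"), inherits(effects, "effect_config"))
  e <- effects
  with_seed(design$seed, {
    N <- e$n_rna; P <- e$n_liver_protein; Q <- e$n_plasma_protein
    genes <- sprintf("g%05d", seq_len(N))

    ## ---- truth classes ----
    n_bio  <- round(e$fraction_secreted_biomarker * N)
    n_anti <- round(e$fraction_antiregulated * N)
    n_de   <- round(e$fraction_de * N)
    if (n_bio > Q) stop("more secreted biomarkers than plasma features")
    if (n_bio + n_anti > P) stop("protein-level classes exceed n_liver_protein")
    class <- rep("null", N)
    idx_bio  <- if (n_bio) sample(Q, n_bio) else integer(0)
    pool_p   <- setdiff(seq_len(P), idx_bio)
    idx_anti <- if (n_anti) sample(pool_p, n_anti) else integer(0)
    pool_all <- setdiff(seq_len(N), c(idx_bio, idx_anti))
    idx_de   <- if (n_de) sample(pool_all, n_de) else integer(0)
    class[idx_bio] <- "secreted_biomarker"
    class[idx_anti] <- "antiregulated"
    class[idx_de] <- "liver_de_only"

    ## ---- effects ----
    rna_eff <- numeric(N)
    nonnull <- class != "null"
    # magnitudes span 0.5x-2x the central effect size (regulated features in
    # such models range over several log2 units), random sign
    mag <- stats::runif(sum(nonnull), 0.5, 2) * e$effect_size_log2
    rna_eff[nonnull] <- sample(c(-1, 1), sum(nonnull), replace = TRUE) * mag
    cc <- e$rna_protein_coupling
    sd_e <- stats::sd(rna_eff[seq_len(P)])
    if (!is.finite(sd_e) || sd_e == 0) sd_e <- e$effect_size_log2
    eta <- stats::rnorm(P, 0, sd_e)
    prot_eff <- numeric(N)
    prot_eff[seq_len(P)] <- cc * rna_eff[seq_len(P)] + sqrt(1 - cc^2) * eta
    prot_eff[idx_anti] <- -prot_eff[idx_anti]          # sign flip vs RNA
    plasma_eff <- numeric(N)
    plasma_eff[idx_bio] <- e$plasma_attenuation * prot_eff[idx_bio]

    ## ---- samples, severity, fibrosis ----
    grid <- expand.grid(animal = seq_len(design$animals_per_group),
                        group = c("control", "diseased"),
                        week = design$weeks, stringsAsFactors = FALSE)
    grid$label <- design$groups[grid$group]
    grid$sample_id <- sprintf("%s_w%02d_a%d", grid$label, grid$week, grid$animal)
    wmax <- max(design$weeks)
    sev_scale <- 4                                      # full-severity anchor
    sev <- ifelse(grid$group == "diseased",
                  sev_scale * grid$week / wmax, 0) +
      stats::rnorm(nrow(grid), 0, e$severity_noise_sd)
    sev <- pmax(sev, 0)
    grid$severity <- sev
    grid$fibrosis_score <- fibrosis_from_severity(
      sev, e$fibrosis_noise_sd, seed = derive_seed(design$seed, "fibrosis"))
    is_w12 <- grid$week == wmax
    grid$batch <- NA_integer_
    # balanced batch assignment within group at the proteomics week
    for (g in unique(grid$group)) {
      sel <- which(is_w12 & grid$group == g)
      grid$batch[sel] <- rep_len(seq_len(design$batches), length(sel))
    }

    ## ---- liver RNA counts (all weeks) ----
    sev_frac <- grid$severity / sev_scale
    rna_base <- stats::rnorm(N, e$rna_base_log2, 1.5)
    log2_mu <- outer(rna_eff, sev_frac) + rna_base      # N x samples
    counts <- matrix(stats::rnbinom(length(log2_mu), mu = 2^log2_mu, size = e$nb_size),
                     nrow = N, dimnames = list(genes, grid$sample_id))
    liver_rna <- omics_matrix(counts, scale = "counts")

    ## ---- proteomics at final week ----
    w12 <- grid[is_w12, , drop = FALSE]
    sf12 <- w12$severity / sev_scale
    make_protein <- function(idx, eff, base_log2, noise_sd) {
      n <- length(idx)
      base <- stats::rnorm(n, base_log2, 1.5)
      sig <- outer(eff[idx], sf12) + base +
        matrix(stats::rnorm(n * nrow(w12), 0, noise_sd), n)
      boff <- matrix(stats::rnorm(n * design$batches, 0, e$batch_sd), n)
      sig <- sig + boff[, w12$batch, drop = FALSE]
      # left-censored missingness: logistic in log2 intensity
      if (e$missing_rate > 0) {
        q <- stats::quantile(sig, e$missing_rate)
        pm <- stats::plogis(e$censoring_steepness * (q - sig))
        sig[stats::runif(length(sig)) < pm] <- NA
      }
      dimnames(sig) <- list(paste0("P_", genes[idx]), w12$sample_id)
      omics_matrix(2^sig, scale = "linear")
    }
    liver_protein  <- make_protein(seq_len(P), prot_eff, e$protein_base_log2, e$protein_noise_sd)
    plasma_protein <- make_protein(seq_len(Q), plasma_eff, e$plasma_base_log2, e$plasma_noise_sd)

    ## ---- id map ----
    has_orth <- stats::runif(N) < e$ortholog_rate
    secreted <- integer(N)
    secreted[idx_bio] <- 1L
    bg <- setdiff(seq_len(N), idx_bio)
    secreted[bg] <- as.integer(stats::runif(length(bg)) < e$secreted_background_rate)
    id_map <- data.frame(
      rat_protein_id = paste0("P_", genes),
      rat_gene_id = genes,
      human_ortholog = ifelse(has_orth, toupper(genes), NA_character_),
      human_protein_id = ifelse(has_orth, paste0("HP_", toupper(genes)), NA_character_),
      secreted = secreted, stringsAsFactors = FALSE)

    truth <- data.frame(
      feature_id = genes, class = class,
      rna_effect = rna_eff, protein_effect = prot_eff, plasma_effect = plasma_eff,
      fibrosis_cor_sign = sign(rna_eff), stringsAsFactors = FALSE)

    annotation <- data.frame(
      sample_id = grid$sample_id, group = grid$label, week = grid$week,
      batch = grid$batch, fibrosis_score = grid$fibrosis_score,
      severity = grid$severity, stringsAsFactors = FALSE)

    structure(list(liver_rna = liver_rna, liver_protein = liver_protein,
                   plasma_protein = plasma_protein, annotation = annotation,
                   id_map = id_map, truth = truth,
                   design = design, effects = e),
              class = "synthetic_study")
  })
}

#' Generate a prior-evidence table
#'
#' Emulates compiled public evidence per gene: a disease-association score in
#' [0, 1] (OpenTargets-like), a long-tailed publication count with an expected
#' count, and two binary flags (patent, curated database). A fraction
#' `evidence_fraction` of the true secreted biomarkers receives elevated
#' evidence; at `evidence_fraction = 0` evidence is independent of truth, so
#' prior-knowledge-only and data-driven rankings can be made to disagree.
#'
#' @param features character vector of gene ids.
#' @param truth truth table from [generate_study()] (or NULL: all background).
#' @param seed integer seed.
#' @param evidence_fraction fraction of secreted biomarkers with elevated
#'   evidence.
#' @return data frame: gene_id, fibrosis_association, pub_count,
#'   expected_count, patent_flag, database_flag.
#' @export
generate_prior_evidence <- function(features, truth = NULL, seed = 1L,
                                    evidence_fraction = 0.8) {
  if (!length(features)) stop("`features` must be non-empty")
  if (!is.null(truth)) {
    unk <- setdiff(features, truth$feature_id)
    if (length(unk)) stop("unknown feature ids: ", paste(utils::head(unk, 5), collapse = ", "))
  }
  with_seed(seed, {
    n <- length(features)
    elevated <- rep(FALSE, n)
    if (!is.null(truth) && evidence_fraction > 0) {
      cls <- truth$class[match(features, truth$feature_id)]
      bio <- which(cls == "secreted_biomarker")
      elevated[sample(bio, round(evidence_fraction * length(bio)))] <- TRUE
    }
    assoc <- ifelse(elevated, stats::rbeta(n, 6, 2), stats::rbeta(n, 1.2, 6))
    pubs <- ifelse(elevated,
                   stats::rnbinom(n, size = 1, mu = 60),
                   stats::rnbinom(n, size = 0.4, mu = 4))
    expected <- stats::rlnorm(n, log(5), 0.6)
    patent <- as.integer(stats::runif(n) < ifelse(elevated, 0.6, 0.04))
    dbflag <- as.integer(stats::runif(n) < ifelse(elevated, 0.6, 0.05))
    data.frame(gene_id = features, fibrosis_association = assoc,
               pub_count = pubs, expected_count = expected,
               patent_flag = patent, database_flag = dbflag,
               stringsAsFactors = FALSE)
  })
}

#' Write a synthetic study to a directory of TSV files
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_omics_tsv(study$liver_rna, file.path(dir, "liver_rna_counts.tsv"))
  write_omics_tsv(study$liver_protein, file.path(dir, "liver_protein_intensity.tsv"))
  write_omics_tsv(study$plasma_protein, file.path(dir, "plasma_protein_intensity.tsv"))
  write_table_tsv(study$annotation, file.path(dir, "annotation.tsv"))
  write_table_tsv(study$id_map, file.path(dir, "id_map.tsv"))
  write_table_tsv(study$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
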