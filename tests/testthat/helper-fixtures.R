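# Shared fixtures: tiny matrices and annotations built in code.

make_ann <- function(samples, groups, week = 12, batch = 1, fibrosis = 0) {
  data.frame(sample_id = samples, group = groups,
             week = rep_len(week, length(samples)),
             batch = rep_len(batch, length(samples)),
             fibrosis_score = rep_len(fibrosis, length(samples)),
             stringsAsFactors = FALSE)
}

# f features x n samples, two balanced groups A/B, optional per-feature
# mean shift in group B
make_log2_matrix <- function(f = 10, n_per_group = 4, shift = 0, sd = 1,
                             seed = 1, batch = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  v <- matrix(rnorm(f * n, 10, sd), f,
              dimnames = list(sprintf("f%03d", 1:f), sprintf("s%02d", 1:n)))
  grp <- rep(c("A", "B"), each = n_per_group)
  v[, grp == "B"] <- v[, grp == "B"] + shift
  m <- omics_matrix(v, scale = "log2")
  list(m = m, ann = make_ann(colnames(v), grp, batch = batch))
}

# fast, small synthetic study for property tests
small_study <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_rna = 150, n_liver_protein = 100, n_plasma_protein = 60,
         fraction_de = 0.1, fraction_secreted_biomarker = 0.05,
         fraction_antiregulated = 0.02),
    list(...))
  generate_study(study_design(animals_per_group = 8, seed = seed),
                 do.call(effect_config, args))
}
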