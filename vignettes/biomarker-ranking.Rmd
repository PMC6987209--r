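---
title: "Multi-dimensional weighted-sum ranking of plasma biomarker candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-dimensional weighted-sum ranking of plasma biomarker candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibromark)
```

## The problem

Preclinical NASH (nonalcoholic steatohepatitis) models — here a rat fed a
choline-deficient L-amino-acid-defined diet with cholesterol (CDAA) against a
choline-supplemented control (CSAA) — develop progressive liver fibrosis that
is normally staged by biopsy histology. A soluble plasma biomarker that
tracks the liver phenotype would let a longitudinal study replace repeated
histology. `fibromark` implements a discovery pipeline for exactly that
setting: liver RNA-Seq over the time course, TMT-style liver and plasma
proteomics at the terminal week, an ordinal fibrosis score per animal, and a
ranking scheme that integrates all of it with prior public evidence.

## The ranking model

Every candidate protein $i$ receives a set of subscores $s_{ij}$ grouped
into four *dimensions*:

| Dimension | Subscores |
|---|---|
| Plasma specificity | plasma differential-expression (dge) score, plasma–fibrosis $r^2$ |
| Liver specificity | liver protein dge, liver RNA dge, liver protein–fibrosis $r^2$, liver RNA–fibrosis $r^2$ |
| Prior evidence | disease-association score, two literature subscores, patent flag, database flag |
| Protein class | secreted flag |

The differential-expression subscore for a contrast is

$$\mathrm{dge} = -\log_{10}(p_\mathrm{adj}) \cdot |\log_2 \mathrm{FC}|,$$

large only for features that are both significant and strongly changed. The
fibrosis subscores are squared Pearson correlations between per-sample
expression and the ordinal fibrosis score (0–4), so they are sign-blind and
already live in $[0,1]$. The total score under a weight setting $w$ is the
multi-linear weighted sum over dimension scores $d_{ij}$:

$$\mathrm{score}_i = \sum_j w_j\, d_{ij}, \qquad \sum_j w_j = 1 .$$

Candidates are the rat proteins that carry a human ortholog in the id map
and were detected, after preprocessing, in **both** the liver and the plasma
protein matrices — the population a translational plasma panel could draw
from.

### Commensurability of subscores

The dge score is unbounded while $r^2$, the association score and the flags
are in $[0,1]$; summing them raw would let the dge terms dominate. We
therefore rank-normalize the three dge subscores and the two literature
inputs over the candidate cohort (average ranks for ties, mapped to
$[0,1]$), use the bounded subscores raw, and define each dimension score as
the *mean* of its subscores. Every dimension then lies in $[0,1]$ and the
weight settings are comparable across dimensions. A `raw_sum = TRUE` flag in
`dimension_scores()` reproduces the literal sum-of-subscores reading; we
make no claim of numeric identity between the two readings, only that the
defaults give a well-conditioned ranking. Missing prior evidence is scored
0 — absence of evidence, never missing-at-random. Final ranks are descending
by total score with stable lexicographic tie-breaking by gene id.

### Sensitivity analysis

Six packaged weight settings (`weight_settings()`) span the design space:
default (0.3/0.3/0.2/0.2 over plasma/liver/prior/secreted), prior knowledge
only (0/0/1/0), balanced (0.2/0.2/0.4/0.2), liver+plasma (0.5/0.5/0/0),
liver only (0/1/0/0) and plasma only (1/0/0/0).
`sensitivity_analysis()` ranks under every setting, reports each candidate's
best (minimum) rank, and orders candidates by hierarchical clustering
(Euclidean, average linkage) of their per-setting score vectors. The
diagnostic readout is qualitative: rankings that use experimental data agree
on a block of top candidates, while the prior-knowledge-only ranking can
diverge completely when public evidence does not reflect the model system.

## Preprocessing

Proteomics matrices pass through the standard TMT sequence, in this order:

1. **Presence filter** — keep a protein with at least `min_present`
   (default 6) observed values in at least one group of 8.
2. **Normalization** — divide each sample column by its total intensity,
   rescale to the mean total, then set each column's mean of observed
   values to 100 (the "channel average of 100" convention).
3. **log2 transform.**
4. **Left-censored imputation** — missing values are intensity-dependent
   (below detection), so they are drawn from a downshifted normal,
   $N(\bar x_j - \delta\, s_j,\ (w\, s_j)^2)$ per sample column $j$;
   defaults $\delta = 2.5, w = 0.2$ for liver and $1.8 / 0.3$ for plasma.
   Drawing from the observed-column distribution shifted left mimics the
   detection limit without inventing signal.
5. **Batch centering** — per-feature mean-centering within each TMT run
   removes additive run offsets exactly; with groups balanced across runs
   it leaves group differences unbiased (this is asserted by a test).

RNA counts are converted to CPM; a gene is *expressed* if CPM ≥ 1 in
strictly more than half the samples of at least one group ("majority" read
strictly; a gene at threshold in exactly half a group's samples is not
expressed). Differential statistics use a pooled-variance two-sided t-test
(Welch behind a flag), Benjamini–Hochberg adjustment, and — for proteomics —
a permutation-based FDR.

### Permutation FDR

For feature $i$ with observed $|t_i|$, the q-value is the mean over label
permutations of the number of null $|t|$ values at or above $|t_i|$,
divided by the number of observed $|t|$ at or above $|t_i|$, capped at 1.
Permutations keep group sizes fixed and are *balanced*: each pseudo-group
draws half its members from each true group, which keeps genuine effects
out of the null distribution. When fewer distinct arrangements exist than
requested, all are enumerated and the result is seed-independent. Ties and
noise can make raw q estimates non-monotone, so a running minimum is swept
from the least significant feature toward the largest $|t|$ — the same
direction as the BH step-up — ensuring q never increases with $|t|$.
We note that sweeping the minimum in the opposite direction (from the
largest $|t|$ downward) would propagate the top feature's q to every weaker
feature and destroy error control; the package deliberately does not do
that, at a measurable cost in nominal power near the significance boundary
(the weakest of many strong planted effects can sit at q ≈ 0.01).

## The synthetic study generator

`generate_study()` emulates the study design so every stage is testable
against ground truth: two diet groups × 8 animals per time point (weeks 4,
8, 12), RNA at every week, proteomics in 2 batches at week 12 only. A
latent per-animal severity (0 for controls, rising with week for diseased)
drives everything: the ordinal 0–4 fibrosis score is a noisy rounded affine
map of severity, and planted expression effects scale with severity.
Feature classes partition the genes: *null*, *liver-DE-only* (RNA effect
plus a coupled liver-protein effect, plasma decoupled), *secreted
biomarker* (liver effect propagated to plasma, attenuated by
`plasma_attenuation`), and *anti-regulated* (liver protein effect flipped
in sign against RNA).

Defaults state the world once: effect sizes are uniform in 0.5–2× a central
`effect_size_log2 = 2` with random sign (regulated features in such models
span several log2 units, and a spread of effect sizes is what makes
feature-level RNA–protein coupling measurable); RNA is negative-binomial
(size 50) so counts carry realistic overdispersion; protein intensities are
log-normal with residual sd 0.3 (TMT-grade precision); the feature-level
correlation between RNA and protein effects is constructed to equal
`rna_protein_coupling` (default 0.75) exactly in expectation; missingness
is logistic in log2 intensity at an overall rate of 5% — higher than a deep
TMT study would show, deliberately, so the presence filter and imputation
paths are exercised; two batches receive independent per-feature offsets
(sd 0.3). Prior evidence is generated per gene with a configurable fraction
of true secreted biomarkers receiving elevated evidence; at fraction 0 the
evidence is independent of truth, which is how the prior-knowledge-only
ranking is made to disagree with data-driven rankings in tests.

What a green test does *not* establish: the generator has no peptide- or
spectrum-level structure, no ratio compression, no shared-peptide protein
inference, no library-size confounding, and its missingness mechanism is a
single smooth logistic. Results on real data depend on all of those.

## Validation stage

`pca_scores()` computes exact SVD PCA of the imputed matrices (features
mean-centered; component signs fixed so the largest-magnitude loading is
positive). The original analysis used probabilistic PCA to tolerate missing
values; since the pipeline already defines imputation, exact SVD is used
instead — deterministic and testable. `marker_pc_regression()` regresses
the first three liver PC score vectors on a candidate's plasma intensity;
for simple regression $r^2$ is the squared Pearson correlation, and in a
well-behaved study the disease axis (PC1) correlates best.
`tissue_enrichment()` scores tissue specificity as median expression in a
tissue over the median of per-tissue medians; a geometric-mean denominator
is available (`denominator = "geomean"`) because the two conventions appear
interchangeably in the literature and cannot be distinguished from
published numbers.

## Numerical and design choices

- Fibrosis is correlated as a numeric variable (Pearson), matching the
  "linear correlation" convention; Spearman is a flag. Correlations use
  pairwise-complete samples so proteomics missingness does not bias $n$.
- The pooled t-test reports NA with a warning on zero-variance features;
  `dge_score()` clamps $p_\mathrm{adj} = 0$ to the smallest positive
  double rather than returning infinity.
- Time-profile clustering z-scores each profile, excludes constant ones,
  and collapses profiles identical after standardization before the
  Euclidean/average-linkage tree is cut, so affine-equivalent profiles can
  never be split.
- All pipeline tables are written with 6-significant-digit formatting and
  fixed column order; a run manifest records parameters, derived per-stage
  seeds (stable hashes of the stage name and the global seed) and md5
  checksums, so identical configs reproduce byte-identical outputs.
- Configuration files are JSON (the R stack here has no YAML reader);
  `exec/fibromark` offers thin `simulate` and `run` shell entry points, but
  the package functions are the primary interface.

## Known limitations

Moderated (empirical-Bayes) variance statistics are intentionally out of
scope, as are spectral search, read alignment, ortholog inference and any
live database queries — id maps and evidence tables arrive as files. The
permutation FDR's nominal power near q = 0.01 is limited by the expected
null exceedances at the weakest true effect (see above); a study designed
to call borderline effects should raise `n_perm` and lower the fold-change
cutoff rather than rely on the boundary.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(seed = 1,
  effects = list(n_rna = 2000, n_liver_protein = 800, n_plasma_protein = 300,
                 fraction_secreted_biomarker = 0.005))
res <- run_pipeline(cfg, out_dir = "run1")
head(res$rankings$default[, c("gene_id", "total", "rank")])
res$recovery
```

The manifest in `run1/manifest.json` reports which of the planted secreted
biomarkers the default ranking recovered in its top 20.
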