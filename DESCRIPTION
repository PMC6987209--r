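Package: fibromark
Title: Multi-Omics Plasma Biomarker Prioritization for Preclinical Liver Fibrosis Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for plasma biomarker discovery in preclinical
    NASH/fibrosis studies. Covers TMT-proteomics style preprocessing
    (group-presence filtering, total-intensity normalization, left-censored
    downshifted imputation, batch mean-centering), RNA-Seq CPM filtering,
    differential statistics with Benjamini-Hochberg and permutation-based FDR,
    per-feature correlation with an ordinal liver-fibrosis score,
    transcript-protein concordance classification, and a multi-dimensional
    weighted-sum candidate ranking with sensitivity analysis over weight
    settings. A seeded synthetic multi-omics study generator with known ground
    truth makes every stage recovery-testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
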