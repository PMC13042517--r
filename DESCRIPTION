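Package: tmekit
Title: Single-Cell Tumor-Microenvironment Analysis of Neoadjuvant Therapy Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, seedable pipeline linking malignant-cell states in the
    tumor microenvironment to neoadjuvant-therapy resistance from paired
    single-cell RNA and TCR sequencing. Provides cell-level quality control and
    library-size normalization, Wilcoxon rank-sum differential expression and
    top-N signature construction, per-cell module scores and single-sample
    rank-based signature scores for bulk cohorts, preranked gene-set enrichment,
    observed-over-expected (Ro/e) tissue and response enrichment with chi-square
    tests, clonotype calling with expansion indices, cross-phenotype clonotype
    overlap and persistence-based clone-fate classification, permutation-tested
    ligand-receptor interaction scoring, and Kaplan-Meier, log-rank, Cox and
    maximally-selected-cutpoint survival analysis. A negative-binomial synthetic
    cohort generator with planted effects makes every stage testable without
    access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
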