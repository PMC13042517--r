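# tmekit

Toolkit for linking malignant-cell states in the tumor microenvironment to
neoadjuvant-therapy response from paired single-cell RNA and TCR sequencing,
with survival follow-through to bulk cohorts. It is aimed at analysts of
multi-patient, multi-tissue oncology cohorts — e.g. esophageal squamous cell
carcinoma treated with neoadjuvant immunochemoradiotherapy — who need the
bespoke statistics of such studies as tested, seedable, reusable functions
rather than one-off scripts.

## What it computes

* **QC and normalization.** Cells kept when detected genes lie strictly
  between configurable bounds (defaults 300 and 8,000) and mitochondrial
  fraction is below 20%; expression normalized as
  `ln(1 + count / cell_total × 10⁴)`.
* **Differential expression and signatures.** Two-sided Wilcoxon rank-sum on
  normalized values (exact for tie-free groups ≤ 8, normal approximation with
  tie correction otherwise), detection (`min.pct`) and `log₂FC` pre-filters,
  Bonferroni adjustment; cluster signatures as the top-40 up-regulated genes.
* **Signature scoring.** Per-cell module scores against expression-matched
  control genes (24 bins, 100 controls per gene); single-sample rank-based
  (ssGSEA-style) scores for bulk cohorts; preranked GSEA with ES, NES and a
  gene-set permutation p-value.
* **Ro/e enrichment.** For a cell-subtype × category table,
  `Ro/e = O / E` with `E = rowsum × colsum / N` (the chi-square expectation);
  `Ro/e > 1` flags preference. Pearson chi-square tests without continuity
  correction.
* **TCR repertoire.** Clonotypes from paired productive full-length TRA/TRB
  CDR3s; clone-size expansion classes (n > 2 vs ≤ 2); expansion index
  `1 − H/ln C` (normalized Shannon entropy of clone sizes); clonotype overlap
  (shared counts, Jaccard); clone fate `TCR_Alive` vs `TCR_Dead` by the
  post-treatment share `n_post/(n_pre+n_post) > 0.3` with a 0.4/0.5/0.6
  sensitivity grid, and its chi-square association with response.
* **Ligand-receptor interactions.** Mean-product score
  `mean(ligand | sender) × mean(receptor | receiver)` with a one-sided
  cluster-label permutation test, significant-pair counting, and a bulk
  fraction-adjusted CD47–SIRPA-style score.
* **Survival.** Kaplan–Meier curves, log-rank tests, two-group Cox hazard
  ratios (Breslow ties), median or maximally-selected-cutpoint
  dichotomization, EFS/OS endpoint construction.
* **Synthetic cohorts.** A seeded generator (negative-binomial counts,
  planted enrichments, planted ligand-receptor coexpression, power-law clone
  repertoires with response-dependent persistence, exponential survival) so
  the whole pipeline is testable without restricted patient data.

## Worked example

```r
library(tmekit)
co <- generate_cohort(cohort_config(rng_seed = 7))
b  <- filter_cells(co$bundle, qc_params(min_genes = 50, max_genes = 420, max_mito = 0.2))
b  <- normalize_bundle(b)

ro_e(make_contingency(b$cell_meta, "cluster", c("response", "tissue")))["Treg", ]
#>    MPR_Normal     MPR_PostT      MPR_PreT NMPR_Adjacent    NMPR_PostT     NMPR_PreT
#>          0.73          0.81          0.91          0.89          1.93          0.80
```

The generator plants a 3-fold regulatory-T-cell enrichment in post-treatment
tumors of non-responders; Ro/e recovers it (1.93 > 1) while all other
categories sit near 1.

```r
lr_permutation_test(b, b$cell_meta$cluster, lr_pair("CD47_SIRPA", "CD47", "SIRPA"),
                    sender = "Epi_PRDM1", receiver = "Mac_LAM",
                    n_perm = 999, rng_seed = 7)
#> CD47-SIRPA score = 19.10, one-sided permutation p = 0.001

ct    <- call_clonotypes(co$contigs, cell_meta = co$tcr_meta)
fates <- classify_clone_fate(ct)
table(fates$fate)
#> TCR_Alive  TCR_Dead
#>       314       226
fate_response_association(attr(fates, "cell_fates"))
#> fate x response chi-square = 371.8, p = 7.48e-83
```

The planted malignant-to-macrophage CD47–SIRPA coexpression is called
significant, and the response-dependent clone persistence (0.7 in responders
vs 0.25 in non-responders) produces the expected strongly significant
fate-by-response association. Survival on the same cohort:

```r
km <- km_estimate(co$survival)
100 * km_surv_at(km, c(12, 36))   # 72.7  50.0  (percent surviving)
cox_hr(co$survival)               # HR (NMPR vs MPR) = 5.10 [1.09, 23.82]
```

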