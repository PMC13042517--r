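---
title: "Methods: models, parameters and design choices in tmekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in tmekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmekit)
```

tmekit packages the computational stages by which a neoadjuvant-therapy
cohort study connects a malignant-cell state to treatment resistance:
quality control and normalization of single-cell counts, differential
expression and signature scoring, composition enrichment (Ro/e), TCR
clonotype fate tracking, permutation-tested ligand-receptor scoring, and
survival analysis. This vignette explains each model, its assumptions and
tunable parameters, the synthetic-data generator that stands in for the
restricted-access patient data, and the design choices made where the
methodology was genuinely open.

## Quality control and normalization

Cells are kept when the number of detected genes lies strictly between
`min_genes` (default 300) and `max_genes` (default 8,000) and the
mitochondrial read fraction is strictly below `max_mito` (default 0.20).
Strict inequalities follow the usual reading of "larger than / lower than"
bounds; the boundary cell at exactly 300 genes is removed. Genes are never
removed and `filter_cells()` is idempotent. Mitochondrial genes are
recognized by the `MT-` symbol prefix (configurable).

Normalization is library-size correction with log transform:
$x_{gc} = \ln\!\left(1 + \frac{n_{gc}}{\sum_g n_{gc}} \cdot s\right)$
with scale factor $s = 10^4$. The scale factor is the single-cell field's
standard convention; it is exposed in `norm_params()` because only the
functional form, not the constant, is canonical. The invariant
$\sum_g (e^{x_{gc}} - 1) = s$ holds per cell to relative tolerance 1e-8 and
is tested.

## Differential expression

`wilcoxon_de()` tests each gene's normalized values between two disjoint
cell groups with a two-sided Wilcoxon rank-sum test. Genes enter the test
only when detected in at least `min_pct` of one group **and**
$|\log_2 \mathrm{FC}| \ge$ `logfc_threshold`, where
$\log_2\mathrm{FC} = \log_2 \frac{\overline{e^{x}-1}_{\text{in}} + 1}{\overline{e^{x}-1}_{\text{out}} + 1}$
(pseudocount 1). Defaults are `min_pct = 0.25`, `logfc_threshold = 0.25`
(the all-cluster marker convention); sensitive two-group contrasts use
0.001/0.001. Choices that the methodology leaves open, resolved here:

* fold-change base 2 (parameterized via `fc_base`);
* Bonferroni adjustment over the genes actually tested (the dominant
  convention for this test in single-cell toolkits);
* exact null enumeration when both groups have ≤ 8 cells and the values are
  tie-free, otherwise the normal approximation with tie correction and no
  continuity correction. The exact branch is validated against an
  independent enumeration oracle over all $\binom{m+n}{m}$ assignments; the
  approximate branch is validated by a null simulation (1,000
  negative-binomial genes, 40 cells per group) whose false-positive rate at
  0.05 must sit inside the binomial 99% band.

Cluster signatures (`signature_from_de()`) are the `n = 40` most
up-regulated genes (positive log-fold-change only), ties broken by smaller
p-value then lexicographic gene id; short results are flagged rather than
padded.

## Signature scoring

`module_score()` follows the expression-matched control-gene scheme: genes
are placed into `n_bins = 24` equal-frequency bins by mean normalized
expression; each signature gene draws `n_ctrl = 100` control genes with
replacement from its bin (one seeded draw per signature gene, in gene-set
order); the cell's score is the mean over signature genes minus the mean
over the pooled control multiset. Scores are exactly zero on a constant
matrix and invariant to adding a constant to all entries — both tested.
Scores are bit-reproducible from `(data, params, rng_seed)`.

`rank_signature_score()` provides a single-sample rank-based statistic for
bulk cohorts in the ssGSEA style: per sample, genes are ordered by
decreasing expression; the running sum gains
$w_i / \sum_{\text{hits}} w_i$ at signature genes (with
$w_i = (N - i + 1)^{\alpha}$, $\alpha = 0.25$) and loses $1/(N - |S|)$
elsewhere; the score is the mean running-sum difference. This deliberately
replaces kernel-CDF GSVA with a simpler statistic of the same monotone
intent; it is compared ordinally, never numerically, to GSVA-derived
results. A constant sample scores 0 and carries a tie flag.

`preranked_gsea()` computes the classic weighted Kolmogorov–Smirnov
enrichment score (signed maximum deviation of hit minus miss CDFs, hit
weights $|w|^{\text{weight\_exp}}$). The null resamples same-size gene sets
(`n_perm` draws) rather than permuting phenotypes, because the score is
applied to single-cell cluster contrasts where phenotype permutation is
ill-defined. NES divides ES by the mean |ES| of same-sign null draws. The
p-value uses the add-one estimator over nulls at least as extreme **in
magnitude**; counting only same-sign nulls would cap p near 0.5 and break
the uniformity of p under the null, which is verified by a KS test over 500
null runs.

## Composition enrichment (Ro/e)

For a cell-subtype × category contingency table,
$\mathrm{Ro/e}_{ij} = O_{ij} / E_{ij}$ with
$E_{ij} = \frac{r_i c_j}{N}$ — the chi-square expected counts. Values above
1 indicate preference of subtype $i$ for category $j$. Exact identities
tested: $\sum_j E_{ij} = r_i$, and each row's column-total-weighted mean of
Ro/e equals 1. Columns may be tissues alone or tissue crossed with response
(`make_contingency(..., col_key = c("response", "tissue"))`); the crossed
layout is the default downstream, since treatment response and timepoint
jointly define the biological condition. Empty rows yield `NA` (not 0 or
∞) when retained deliberately. `chi_square_test()` reports the raw Pearson
statistic without Yates correction — consistent with the Ro/e expectation
model — with a flag when any expected count is below 5; a corrected variant
is available by argument.

## TCR repertoire and clone fate

Cells are assigned a clonotype only when they carry at least one
productive, full-length TRA **and** TRB; the highest-UMI chain per type is
used (ties to the lexicographically smaller CDR3 for determinism).
Clonotype identity defaults to the nucleotide CDR3 pair — the stricter 10x
convention — with amino-acid level by flag; both sequences are preserved so
the choice can be revisited downstream.

Clone sizes are computed within patient (clones are not merged across
patients; cross-individual TCR sharing is biologically exceptional), and
this scope is configurable. The expansion index of a group is
$1 - H/\ln C$, with $H$ the Shannon entropy of clonotype frequencies and
$C$ the number of distinct clonotypes: 0 for a perfectly even repertoire,
1 for a monoclonal one; groups under 2 cells give `NA`.

Clone fate over treatment: within patient, a clone with $n_{pre}$ baseline
and $n_{post}$ post-treatment cells has persistence ratio
$n_{post}/(n_{pre}+n_{post})$ and is `TCR_Alive` when the ratio strictly
exceeds the threshold (default 0.3), `TCR_Dead` otherwise; clones unseen at
baseline are excluded by default since fate is about persistence from
baseline. The ratio uses raw cell counts by default; a
compartment-frequency-normalized mode exists behind `frequency_mode`
because both phrasings circulate for this statistic. The sensitivity grid
0.4/0.5/0.6 is built in, and the nesting
$\mathrm{Alive}_{0.6} \subseteq \mathrm{Alive}_{0.5} \subseteq \mathrm{Alive}_{0.4}$
is a tested invariant. Fate-by-response association is the Pearson
chi-square on the 2×2 table of cell counts.

## Ligand-receptor interactions

The interaction score of pair $(L, R)$ from sender cluster $S$ to receiver
$R$ is the product of mean normalized expressions,
$\bar{x}_{L|S} \cdot \bar{x}_{R|\mathcal{R}}$. This mean-product score with
a full cluster-label permutation null deliberately replaces mass-action
communication models: downstream claims rest only on the ranking and
significance of pairs, and the permutation test is the stated inferential
device. The one-sided p-value uses the add-one estimator
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{perm})$, so p is never 0
and has granularity $1/(n_{perm}+1)$; calibration under an exchangeable
null is tested against the binomial 99% band at $\alpha = 0.05$.

The cohort-level "fraction-adjusted" bulk score multiplies ligand and
receptor expression by min-max-rescaled sender/receiver signature scores
standing in for cell fractions. The exact normalization of such adjustment
is not canonical; this surrogate is a declared convention — the only
cohort-internal quantity available from bulk data — not a reconstruction of
any particular tool.

## Survival

Kaplan–Meier estimation, log-rank tests and the two-group Cox model are
delegated to the survival package (product-limit estimator; hypergeometric-
variance log-rank; Breslow handling of tied event times, the simplest
correct choice). `cox_hr()` returns a divergence flag instead of a number
when one group has no events (monotone likelihood). Confidence bands use
the log(−log) transform.

`dichotomize()` splits subjects at the median (strictly-greater = "high")
or at the maximally selected cutpoint: among observed score values leaving
at least `min_prop = 0.1` of subjects on each side, the one maximizing the
absolute standardized log-rank statistic, ties to the lower value. The
reported p-value at the chosen cutpoint is labeled uncorrected — no
adjustment is made for having searched. On planted two-group fixtures
(hazard ratio 3 between score halves, 100 subjects), the selected cutpoint
has a median error of about 2 ranks but a heavy-tailed error distribution;
the package's recovery criterion is therefore that the cutpoint falls
within ±10% of the cohort size of the planted boundary in at least 90% of
seeded replicates, which the suite verifies. A ±1-rank criterion is not
achievable at this effect size and does not improve with cohort size.

EFS takes the first of progression, recurrence, metastasis or death; OS
takes death; subjects without the event are censored at last follow-up.

## The synthetic cohort generator

`generate_cohort()` emulates the study design the pipeline targets: 9
patients (5 responders, 4 non-responders), 26 samples across Normal,
Adjacent, pre- and post-treatment tumor tissue. Scales are reduced for
speed — 120 cells per sample and a universe of ~420 genes by default — so
the full pipeline runs in seconds; tests state their sizes explicitly.

* **Counts** are negative binomial (dispersion `size = 2`) with gene
  baseline means drawn log-normal, per-cell library factors log-normal
  (sdlog 0.3), 10 marker genes per cluster boosted by `log2fc = 2`, and 10
  `MT-` genes tuned to a ~5% mitochondrial fraction. This is the standard
  scRNA-seq noise model; the generator documents its own assumptions since
  no explicit noise model is canonical for the real data.
* **Composition** follows per-sample cluster proportions; planted
  enrichments multiply a cluster's proportion in matching conditions and
  renormalize, so the Ro/e ground truth is computable analytically. The
  default plants a 3-fold regulatory-T-cell enrichment in post-treatment
  non-responder tumors.
* **Ligand-receptor plants** multiply ligand mean in the sender and
  receptor mean in the receiver by 8 (defaults: CD47–SIRPA
  epithelial→macrophage, IL1A–IL1R2 epithelial→Treg).
* **Repertoires** draw 60 clones per patient with power-law sizes
  (exponent 2.5, capped at 30 cells); each baseline clone persists with
  probability 0.7 (responders) or 0.25 (non-responders); persisting clones
  resample Poisson post-treatment counts, dying clones thin to a 0.15
  binomial rate. This gives direct control of the expected `TCR_Alive`
  fraction per response group.
* **Survival** is exponential per group (defaults 0.004/0.035 events per
  month for responders/non-responders) with administrative censoring at
  44.4 months, the cohort's median follow-up scale.

What the generator does **not** emulate: batch effects, doublets, ambient
RNA, cell-cycle structure, spatial organization, and realistic gene-gene
correlation beyond cluster means. Passing recovery tests therefore shows
the statistics detect their target effects under idealized noise, not that
they are robust to every artifact of real data.

## Numerical conventions

* All stochastic routines take explicit seeds and restore the caller's RNG
  state; derived stream seeds stay within 32-bit integer range.
* Permutation p-values always use the add-one estimator.
* MTX files are 1-based on disk (Matrix Market standard); indices are
  converted at the reader boundary. Barcodes are joined to metadata after
  stripping the 10x `-1` suffix (configurable).
* Degenerate inputs error early with the offending label named: zero-total
  cells at normalization, zero row/column totals in Ro/e, empty groups in
  DE, all-equal scores at dichotomization.

## Known limitations

Clustering, embedding, batch integration, doublet detection, copy-number
inference and trajectory analysis are intentionally out of scope — cluster
labels are an input. The bulk signature score is ordinal, not a numerical
GSVA reimplementation. The maximally selected cutpoint's p-value is not
corrected for the search. Multi-subunit receptor complexes and
pathway-level aggregation of ligand-receptor results are not modeled.
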