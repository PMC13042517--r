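# Cell-level quality control, library-size normalization, Wilcoxon rank-sum
# differential expression and top-N signature construction.

#' Quality-control parameters
#'
#' Cells are retained when strictly more than `min_genes` and strictly fewer
#' than `max_genes` genes are detected, and the mitochondrial read fraction
#' is strictly below `max_mito`.
#'
#' @param min_genes Lower bound on detected genes (default 300, exclusive).
#' @param max_genes Upper bound on detected genes (default 8000, exclusive).
#' @param max_mito Upper bound on mitochondrial fraction (default 0.20,
#'   exclusive).
#' @return A list of class `QCParams`.
#' @export
qc_params <- function(min_genes = 300, max_genes = 8000, max_mito = 0.20) {
  if (!(min_genes > 0 && min_genes < max_genes))
    stop_validation("need 0 < min_genes < max_genes")
  if (!(max_mito > 0 && max_mito <= 1))
    stop_validation("need 0 < max_mito <= 1")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito = max_mito), class = "QCParams")
}

#' Filter low-quality cells
#'
#' Applies the two QC rules of [qc_params()] to the per-cell statistics
#' (computed from counts at bundle construction). Genes are never removed
#' and cell order is preserved; the operation is idempotent.
#'
#' @param bundle An `ExpressionBundle`.
#' @param params A `QCParams` object.
#' @return The filtered bundle. If every cell fails QC, the empty bundle is
#'   returned with a warning and attribute `empty_result = TRUE`.
#' @export
filter_cells <- function(bundle, params = qc_params()) {
  stopifnot(inherits(bundle, "ExpressionBundle"), inherits(params, "QCParams"))
  m <- bundle$cell_meta
  keep <- m$n_genes_detected > params$min_genes &
    m$n_genes_detected < params$max_genes &
    m$mito_fraction < params$max_mito
  out <- subset_cells(bundle, keep)
  if (ncol(bundle$counts) > 0L && !any(keep)) {
    warning("all ", ncol(bundle$counts), " cells removed by QC")
    attr(out, "empty_result") <- TRUE
  }
  out
}

#' Normalization parameters
#' @param scale_factor Per-cell library size after rescaling (default 1e4).
#' @return A list of class `NormParams`.
#' @export
norm_params <- function(scale_factor = 1e4) {
  if (!(is.numeric(scale_factor) && scale_factor > 0))
    stop_validation("scale_factor must be positive")
  structure(list(scale_factor = scale_factor), class = "NormParams")
}

#' Library-size normalization with log transform
#'
#' Fills the bundle's `normalized` slot with
#' `ln(1 + count / cell_total * scale_factor)`; raw counts are untouched.
#' Every cell must have a positive total (QC should have removed empties).
#'
#' @param bundle An `ExpressionBundle`.
#' @param params A `NormParams` object.
#' @return The bundle with `normalized` present.
#' @export
normalize_bundle <- function(bundle, params = norm_params()) {
  stopifnot(inherits(bundle, "ExpressionBundle"), inherits(params, "NormParams"))
  totals <- Matrix::colSums(bundle$counts)
  if (any(totals == 0)) {
    bad <- bundle$cell_ids[totals == 0][1]
    stop_validation("cell '", bad, "' has zero total count; run filter_cells first")
  }
  norm <- bundle$counts
  if (length(norm@x)) {
    percell <- rep.int(seq_len(ncol(norm)), diff(norm@p))
    norm@x <- log1p(norm@x / totals[percell] * params$scale_factor)
  }
  bundle$normalized <- norm
  bundle
}

#' Differential-expression parameters
#'
#' @param min_pct Minimum detection fraction in at least one group for a
#'   gene to be tested (default 0.25, the all-marker convention; two-group
#'   contrasts in the source workflow use 0.001).
#' @param logfc_threshold Minimum |log2 fold change| to test (default 0.25).
#' @param pseudocount Added to group means before the ratio (default 1).
#' @param fc_base Base of the fold-change logarithm (default 2).
#' @return A list of class `DEParams`.
#' @export
de_params <- function(min_pct = 0.25, logfc_threshold = 0.25,
                      pseudocount = 1, fc_base = 2) {
  if (!(min_pct >= 0 && min_pct <= 1)) stop_validation("min_pct must lie in [0, 1]")
  if (logfc_threshold < 0) stop_validation("logfc_threshold must be >= 0")
  if (pseudocount <= 0) stop_validation("pseudocount must be positive")
  structure(list(min_pct = min_pct, logfc_threshold = logfc_threshold,
                 pseudocount = pseudocount, fc_base = fc_base),
            class = "DEParams")
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' For each gene passing the detection and fold-change pre-filters, tests
#' the normalized values of the in-group against the out-group with a
#' two-sided Wilcoxon rank-sum test. Fold change is
#' `log2((mean(expm1(norm)) + pseudocount) / (same, out-group))`. The exact
#' null distribution is enumerated when both groups have at most 8 cells and
#' the values are tie-free; otherwise the normal approximation with tie
#' correction is used. P-values are Bonferroni-adjusted over the genes
#' actually tested.
#'
#' @param bundle A normalized `ExpressionBundle`.
#' @param group_in,group_out Disjoint, nonempty cell masks (logical, index
#'   or cell-id vectors).
#' @param params A `DEParams` object.
#' @return A data frame with columns `gene_id`, `log2fc`, `pct_in`,
#'   `pct_out`, `p_value`, `p_adjusted`, sorted by increasing p then
#'   decreasing |log2fc|. Zero rows (all genes filtered) is a valid result.
#' @export
wilcoxon_de <- function(bundle, group_in, group_out, params = de_params()) {
  stopifnot(inherits(bundle, "ExpressionBundle"), inherits(params, "DEParams"))
  if (is.null(bundle$normalized))
    stop_validation("bundle has no normalized matrix; run normalize_bundle first")
  resolve <- function(g) {
    if (is.logical(g)) which(g)
    else if (is.character(g)) match(g, bundle$cell_ids)
    else as.integer(g)
  }
  gi <- resolve(group_in); go <- resolve(group_out)
  if (!length(gi) || !length(go)) stop_validation("both groups must be nonempty")
  if (length(intersect(gi, go))) stop_validation("group masks must be disjoint")

  X <- bundle$normalized
  in_m <- X[, gi, drop = FALSE]
  out_m <- X[, go, drop = FALSE]
  pct_in <- Matrix::rowSums(in_m > 0) / length(gi)
  pct_out <- Matrix::rowSums(out_m > 0) / length(go)
  mean_in <- Matrix::rowSums(expm1(in_m)) / length(gi)
  mean_out <- Matrix::rowSums(expm1(out_m)) / length(go)
  lfc <- log(mean_in + params$pseudocount, base = params$fc_base) -
    log(mean_out + params$pseudocount, base = params$fc_base)

  test <- pmax(pct_in, pct_out) >= params$min_pct & abs(lfc) >= params$logfc_threshold
  idx <- which(test)
  if (!length(idx))
    return(data.frame(gene_id = character(), log2fc = numeric(),
                      pct_in = numeric(), pct_out = numeric(),
                      p_value = numeric(), p_adjusted = numeric()))
  pvals <- vapply(idx, function(g) {
    x <- in_m[g, ]; y <- out_m[g, ]
    wilcox_p(x, y)
  }, numeric(1))
  res <- data.frame(gene_id = bundle$gene_ids[idx], log2fc = lfc[idx],
                    pct_in = pct_in[idx], pct_out = pct_out[idx],
                    p_value = pvals,
                    p_adjusted = pmin(1, pvals * length(idx)),
                    stringsAsFactors = FALSE)
  res[order(res$p_value, -abs(res$log2fc), res$gene_id), , drop = FALSE]
}

# Two-sided rank-sum p-value: exact enumeration for small tie-free groups,
# normal approximation with tie correction otherwise.
wilcox_p <- function(x, y) {
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && length(x) <= 8 && length(y) <= 8) {
    stats::wilcox.test(x, y, exact = TRUE)$p.value
  } else {
    stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  }
}

#' Build a cluster signature from differential-expression results
#'
#' Takes the `n` most up-regulated genes (largest log2 fold change, positive
#' only); ties broken by smaller p-value, then lexicographic gene id. When
#' fewer than `n` genes qualify all are returned and the result carries
#' attribute `short_set = TRUE`.
#'
#' @param de A data frame from [wilcoxon_de()].
#' @param n Signature size (default 40).
#' @return Character vector of gene ids (a gene set).
#' @export
signature_from_de <- function(de, n = 40) {
  if (!nrow(de)) stop_validation("no DE records to build a signature from")
  up <- de[de$log2fc > 0, , drop = FALSE]
  up <- up[order(-up$log2fc, up$p_value, up$gene_id), , drop = FALSE]
  sig <- utils::head(up$gene_id, n)
  if (length(sig) < n) attr(sig, "short_set") <- TRUE
  sig
}
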