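# Signature scoring: per-cell module scores against expression-matched
# control genes, per-sample rank-based enrichment for bulk cohorts, and
# preranked GSEA with a gene-set permutation null.

#' Module-score parameters
#'
#' @param n_bins Number of expression bins for control matching (default 24).
#' @param n_ctrl Control genes sampled (with replacement) per signature gene
#'   (default 100).
#' @param rng_seed Seed driving the control draws.
#' @return A list of class `ScoreParams`.
#' @export
score_params <- function(n_bins = 24, n_ctrl = 100, rng_seed = 1L) {
  if (n_bins < 2) stop_validation("n_bins must be >= 2")
  if (n_ctrl < 1) stop_validation("n_ctrl must be >= 1")
  structure(list(n_bins = n_bins, n_ctrl = n_ctrl,
                 rng_seed = as.integer(rng_seed)), class = "ScoreParams")
}

# Equal-frequency expression bins: genes ranked by mean normalized
# expression, cut into n_bins groups of (near-)equal size.
expression_bins <- function(avg, n_bins) {
  r <- rank(avg, ties.method = "first")
  as.integer(ceiling(r / (length(avg) / n_bins)))
}

#' Per-cell module score for a gene signature
#'
#' Genes are binned into `n_bins` equal-frequency bins by mean normalized
#' expression across cells. For each signature gene, `n_ctrl` control genes
#' are drawn with replacement from its bin (seeded draw, one per signature
#' gene, in gene-set order). The score of a cell is the mean normalized
#' expression over signature genes minus the mean over the pooled control
#' draw (duplicates counted as drawn).
#'
#' @param bundle A normalized `ExpressionBundle`.
#' @param gene_set Character vector of gene ids.
#' @param params A `ScoreParams` object.
#' @return Named numeric vector of per-cell scores. Signature genes missing
#'   from the matrix are dropped with a warning; if all are missing this is
#'   an error listing them.
#' @export
module_score <- function(bundle, gene_set, params = score_params()) {
  stopifnot(inherits(bundle, "ExpressionBundle"), inherits(params, "ScoreParams"))
  if (is.null(bundle$normalized))
    stop_validation("bundle has no normalized matrix; run normalize_bundle first")
  present <- gene_set[gene_set %in% bundle$gene_ids]
  if (!length(present))
    stop_validation("no signature gene present in matrix; missing: ",
                    paste(gene_set, collapse = ", "))
  if (length(present) < length(gene_set))
    warning(length(gene_set) - length(present), " signature gene(s) absent from matrix")

  X <- bundle$normalized
  avg <- Matrix::rowMeans(X)
  bins <- expression_bins(avg, params$n_bins)
  names(bins) <- bundle$gene_ids

  ctrl <- with_seed(params$rng_seed, {
    unlist(lapply(present, function(g) {
      pool <- bundle$gene_ids[bins == bins[[g]]]
      pool[sample.int(length(pool), params$n_ctrl, replace = TRUE)]
    }), use.names = FALSE)
  })
  sig_mean <- Matrix::colMeans(X[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(X[ctrl, , drop = FALSE])
  out <- as.numeric(sig_mean - ctrl_mean)
  names(out) <- bundle$cell_ids
  out
}

#' Single-sample rank-based signature score for bulk expression
#'
#' A single-sample enrichment statistic in the ssGSEA style. Per sample,
#' genes are ordered by decreasing expression; the running sum gains
#' `rank_weight^alpha / sum(rank_weight^alpha over the set)` at signature
#' genes (rank_weight = N - position + 1) and loses `1 / (N - |S|)` at the
#' rest. The score is the mean running-sum difference over all positions,
#' comparable across samples sharing a gene universe.
#'
#' @param bulk Numeric matrix, samples x genes, with gene names as columns.
#' @param gene_set Character vector of gene ids (>= 2 must be present).
#' @param alpha Rank-weight exponent (default 0.25).
#' @return Named numeric vector of per-sample scores. A constant sample
#'   (all genes tied) scores 0 and is flagged in attribute `tie_flag`.
#' @export
rank_signature_score <- function(bulk, gene_set, alpha = 0.25) {
  stopifnot(is.matrix(bulk), !is.null(colnames(bulk)))
  hit <- colnames(bulk) %in% gene_set
  if (sum(hit) < 2)
    stop_validation("fewer than 2 signature genes present in bulk matrix")
  n <- ncol(bulk)
  ties <- logical(nrow(bulk))
  scores <- vapply(seq_len(nrow(bulk)), function(s) {
    x <- bulk[s, ]
    if (length(unique(x)) == 1L) { ties[s] <<- TRUE; return(0) }
    ord <- order(x, decreasing = TRUE)
    is_hit <- hit[ord]
    w <- (n - seq_len(n) + 1)^alpha
    p_hit <- cumsum(ifelse(is_hit, w, 0)) / sum(w[is_hit])
    p_miss <- cumsum(!is_hit) / (n - sum(hit))
    mean(p_hit - p_miss)
  }, numeric(1))
  names(scores) <- rownames(bulk)
  attr(scores, "tie_flag") <- ties
  scores
}

#' Preranked gene-set enrichment
#'
#' Computes the classic weighted Kolmogorov-Smirnov enrichment score (signed
#' maximum deviation of the hit CDF minus miss CDF, hits weighted by
#' |weight|^`weight_exp`), a normalized score against a gene-set resampling
#' null, a one-sided permutation p-value with the add-one estimator, and the
#' leading-edge genes.
#'
#' @param ranked_genes Character vector of unique gene ids, ordered from the
#'   top of the ranking.
#' @param weights Numeric ranking statistic parallel to `ranked_genes`.
#' @param gene_set Character vector; its intersection with `ranked_genes`
#'   must contain >= 2 genes.
#' @param weight_exp Weighting exponent (0 = unweighted KS, 1 = classic).
#' @param n_perm Number of random same-size gene sets for the null.
#' @param rng_seed Seed for the null draws.
#' @return A list of class `GseaResult` with `es`, `nes`, `p_value`,
#'   `leading_edge`, `n_perm`.
#' @export
preranked_gsea <- function(ranked_genes, weights = rev(seq_along(ranked_genes)),
                           gene_set, weight_exp = 1, n_perm = 999,
                           rng_seed = 1L) {
  if (anyDuplicated(ranked_genes)) stop_validation("ranked_genes must be unique")
  hit <- ranked_genes %in% gene_set
  k <- sum(hit)
  if (k < 2) stop_validation("gene set shares fewer than 2 genes with the ranking")

  es_obs <- gsea_es(which(hit), weights, weight_exp)
  null_es <- with_seed(rng_seed, {
    vapply(seq_len(n_perm), function(i) {
      gsea_es(sort(sample.int(length(ranked_genes), k)), weights, weight_exp)
    }, numeric(1))
  })
  same_sign <- null_es[sign(null_es) == sign(es_obs)]
  nes <- if (length(same_sign)) es_obs / mean(abs(same_sign)) else NA_real_
  p <- (1 + sum(abs(null_es) >= abs(es_obs))) / (1 + n_perm)

  running <- gsea_running(which(hit), weights, weight_exp, length(ranked_genes))
  peak <- if (es_obs >= 0) which.max(running) else which.min(running)
  le <- if (es_obs >= 0) ranked_genes[hit & seq_along(hit) <= peak]
        else ranked_genes[hit & seq_along(hit) >= peak]
  structure(list(es = es_obs, nes = nes, p_value = p, leading_edge = le,
                 n_perm = n_perm), class = "GseaResult")
}

# Running hit-minus-miss sum over positions 1..n.
gsea_running <- function(hit_pos, weights, weight_exp, n = length(weights)) {
  w <- rep(0, n)
  w[hit_pos] <- abs(weights[hit_pos])^weight_exp
  denom <- sum(w)
  if (denom == 0) { w[hit_pos] <- 1; denom <- length(hit_pos) }
  miss <- rep(1 / (n - length(hit_pos)), n)
  miss[hit_pos] <- 0
  cumsum(w / denom - miss)
}

gsea_es <- function(hit_pos, weights, weight_exp) {
  run <- gsea_running(hit_pos, weights, weight_exp)
  run[which.max(abs(run))]
}

#' @export
print.GseaResult <- function(x, ...) {
  cat(sprintf("GSEA: ES = %.4f, NES = %.4f, p = %.4g (%d permutations)\n",
              x$es, x$nes, x$p_value, x$n_perm))
  cat("  leading edge:", length(x$leading_edge), "genes\n")
  invisible(x)
}
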