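# Ligand-receptor interaction scoring between annotated clusters: a
# mean-product score, a one-sided label-permutation test, significant-pair
# counting, and a cohort-level fraction-adjusted score for bulk data.

#' Define a ligand-receptor pair
#'
#' @param name Display name (e.g. "CD47_SIRPA").
#' @param ligand,receptor Gene ids. A pair with ligand == receptor is
#'   permitted but flagged with attribute `self_pair`.
#' @return A list of class `LRPair`.
#' @export
lr_pair <- function(name, ligand, receptor) {
  if (!nzchar(ligand) || !nzchar(receptor))
    stop_validation("both ligand and receptor must be named")
  out <- structure(list(name = name, ligand = ligand, receptor = receptor),
                   class = "LRPair")
  if (ligand == receptor) attr(out, "self_pair") <- TRUE
  out
}

#' Read a 3-column TSV of ligand-receptor pairs (name, ligand, receptor)
#' @param path TSV path.
#' @return List of `LRPair` objects.
#' @export
read_lr_pairs <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop_format("LR pair file needs 3 columns: name, ligand, receptor")
  lapply(seq_len(nrow(df)), function(i) lr_pair(df[i, 1], df[i, 2], df[i, 3]))
}

#' Mean-product ligand-receptor interaction score
#'
#' `mean normalized ligand expression in the sender cluster x mean
#' normalized receptor expression in the receiver cluster`. Invariant to
#' duplicating cells within a cluster.
#'
#' @param bundle A normalized `ExpressionBundle`.
#' @param clusters Per-cell cluster labels (defaults to
#'   `bundle$cell_meta$cluster`).
#' @param pair An `LRPair`.
#' @param sender,receiver Cluster labels.
#' @return Non-negative scalar.
#' @export
lr_score <- function(bundle, clusters = bundle$cell_meta$cluster, pair,
                     sender, receiver) {
  stopifnot(inherits(bundle, "ExpressionBundle"), inherits(pair, "LRPair"))
  if (is.null(bundle$normalized))
    stop_validation("bundle has no normalized matrix; run normalize_bundle first")
  missing <- setdiff(c(pair$ligand, pair$receptor), bundle$gene_ids)
  if (length(missing))
    stop_validation("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  s <- which(clusters == sender); r <- which(clusters == receiver)
  if (!length(s) || !length(r))
    stop_validation("empty cluster: ", if (!length(s)) sender else receiver)
  mean(bundle$normalized[pair$ligand, s]) * mean(bundle$normalized[pair$receptor, r])
}

#' One-sided permutation test of a ligand-receptor score
#'
#' The null shuffles cluster labels across all cells (sizes preserved) and
#' recomputes the score; `p = (1 + #\{null >= observed\}) / (1 + n_perm)`
#' (add-one estimator, so p is never 0 and has granularity 1/(n_perm+1)).
#'
#' @inheritParams lr_score
#' @param n_perm Number of permutations (>= 99).
#' @param rng_seed Seed; results are bit-reproducible given (data, seed).
#' @param alpha Significance level recorded in the result (default 0.05).
#' @return List of class `InteractionResult`: `pair`, `sender`, `receiver`,
#'   `score`, `p_value`, `significant`, `n_perm`.
#' @export
lr_permutation_test <- function(bundle, clusters = bundle$cell_meta$cluster,
                                pair, sender, receiver, n_perm = 999,
                                rng_seed = 1L, alpha = 0.05) {
  if (n_perm < 99) stop_validation("n_perm must be >= 99")
  obs <- lr_score(bundle, clusters, pair, sender, receiver)
  lig <- as.numeric(bundle$normalized[pair$ligand, ])
  rec <- as.numeric(bundle$normalized[pair$receptor, ])
  n_s <- sum(clusters == sender); n_r <- sum(clusters == receiver)
  n <- length(clusters)
  null <- with_seed(rng_seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      mean(lig[idx[seq_len(n_s)]]) * mean(rec[idx[n_s + seq_len(n_r)]])
    }, numeric(1))
  })
  p <- (1 + sum(null >= obs)) / (1 + n_perm)
  structure(list(pair = pair$name, sender = sender, receiver = receiver,
                 score = obs, p_value = p, significant = p < alpha,
                 n_perm = n_perm, alpha = alpha),
            class = "InteractionResult")
}

#' Count significant ligand-receptor pairs per cluster pair
#'
#' @param results List of `InteractionResult` objects sharing one alpha.
#' @param alpha Significance level (default 0.05; `p < alpha`).
#' @return Data frame `sender`, `receiver`, `n_significant`, one row per
#'   observed (sender, receiver) combination; invariant to result order.
#' @export
count_significant_pairs <- function(results, alpha = 0.05) {
  sender <- vapply(results, `[[`, character(1), "sender")
  receiver <- vapply(results, `[[`, character(1), "receiver")
  p <- vapply(results, `[[`, numeric(1), "p_value")
  key <- paste(sender, receiver, sep = "\r")
  agg <- tapply(p < alpha, key, sum)
  ids <- sort(names(agg))
  out <- data.frame(sender = sub("\r.*$", "", ids),
                    receiver = sub("^.*\r", "", ids),
                    n_significant = as.integer(agg[ids]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cohort-level fraction-adjusted interaction score for bulk expression
#'
#' Per sample: `ligand expression x receptor expression x f_sender x
#' f_receiver`, where the f terms are the sender/receiver signature scores
#' ([rank_signature_score()]) min-max rescaled to \[0, 1\] across the
#' cohort, standing in for the two cell-type fractions.
#'
#' @param bulk Samples x genes matrix with gene names.
#' @param pair An `LRPair` whose genes are columns of `bulk`.
#' @param sender_signature,receiver_signature Gene sets (>= 2 genes present
#'   each).
#' @param alpha Rank-weight exponent passed to [rank_signature_score()].
#' @return Named per-sample numeric vector.
#' @export
adjusted_interaction_score <- function(bulk, pair, sender_signature,
                                       receiver_signature, alpha = 0.25) {
  if (nrow(bulk) < 2)
    stop_validation("cohort rescaling needs >= 2 samples")
  missing <- setdiff(c(pair$ligand, pair$receptor), colnames(bulk))
  if (length(missing))
    stop_validation("gene(s) absent from bulk matrix: ", paste(missing, collapse = ", "))
  rescale01 <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) rep(0, length(x)) else (x - rng[1]) / diff(rng)
  }
  f_s <- rescale01(as.numeric(rank_signature_score(bulk, sender_signature, alpha)))
  f_r <- rescale01(as.numeric(rank_signature_score(bulk, receiver_signature, alpha)))
  out <- bulk[, pair$ligand] * bulk[, pair$receptor] * f_s * f_r
  names(out) <- rownames(bulk)
  out
}
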