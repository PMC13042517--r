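# Shared fixture builders: all test data is constructed in code.

# Fresh scratch directory per call (under the session tempdir).
withr_tempdir <- function() {
  d <- tempfile("fixture")
  dir.create(d)
  d
}

# Dense matrix -> validated bundle with optional metadata columns.
make_bundle <- function(counts, meta = NULL, ...) {
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("c%02d", seq_len(ncol(counts)))
  expression_bundle(counts, cell_meta = meta, ...)
}

# Random integer bundle with cluster labels, normalized.
random_bundle <- function(n_genes = 30, n_cells = 40, seed = 1,
                          clusters = c("A", "B")) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_cells, size = 2, mu = 3), n_genes, n_cells)
  m[1, ] <- m[1, ] + 1L            # guarantee positive totals
  meta <- data.frame(cluster = rep_len(clusters, n_cells))
  normalize_bundle(make_bundle(m, meta))
}

# Minimal contig table (one row per chain).
make_contigs <- function(barcode, chain, cdr3_nt, cdr3_aa = cdr3_nt,
                         productive = TRUE, full_length = TRUE, umis = 3L) {
  data.frame(barcode = barcode, chain = chain, cdr3_nt = cdr3_nt,
             cdr3_aa = cdr3_aa, productive = productive,
             full_length = full_length, umis = umis,
             stringsAsFactors = FALSE)
}

# Clonotype table straight from per-cell vectors (bypasses contig calling).
make_clonotable <- function(clonotype_id, patient_id = "P01",
                            timepoint = "PreT", response = "MPR",
                            cluster = "CD8") {
  n <- length(clonotype_id)
  df <- data.frame(cell_id = sprintf("cell%03d", seq_len(n)),
                   clonotype_id = clonotype_id,
                   cdr3a = clonotype_id, cdr3b = clonotype_id,
                   patient_id = rep_len(patient_id, n),
                   timepoint = rep_len(timepoint, n),
                   response = rep_len(response, n),
                   cluster = rep_len(cluster, n),
                   stringsAsFactors = FALSE)
  class(df) <- c("ClonotypeTable", "data.frame")
  df
}

# Exact two-sided rank-sum p-value by enumeration over all C(m+n, m)
# assignments (independent oracle for wilcoxon_de).
exact_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  m <- length(x)
  w_obs <- sum(r[seq_len(m)])
  combs <- utils::combn(length(pooled), m)
  w_all <- apply(combs, 2, function(i) sum(r[i]))
  lo <- mean(w_all <= w_obs); hi <- mean(w_all >= w_obs)
  min(1, 2 * min(lo, hi))
}

# Brute-force GSEA running sum (independent of the package's implementation).
brute_es <- function(n, hit_pos, weights = rep(1, n), weight_exp = 0) {
  run <- 0; best <- 0
  w <- abs(weights)^weight_exp
  denom <- sum(w[hit_pos])
  for (i in seq_len(n)) {
    run <- run + if (i %in% hit_pos) w[i] / denom else -1 / (n - length(hit_pos))
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Breslow-ties two-group Cox partial log-likelihood (for grid-search oracle).
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + beta * sum(x[d]) - length(d) * log(sum(exp(beta * x[risk])))
  }
  ll
}
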