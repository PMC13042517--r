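# Module scores, bulk rank signature scores and preranked GSEA against
# closed forms and brute-force oracles.

test_that("module_score closed cases: constant matrix and shift invariance", {
  m <- matrix(3L, 20, 10, dimnames = list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:10)))
  b <- make_bundle(m)
  b$normalized <- b$counts                     # constant normalized matrix
  sc <- module_score(b, c("g01", "g05"), score_params(n_bins = 2, rng_seed = 1))
  expect_equal(unname(sc), rep(0, 10))         # signature mean == control mean

  set.seed(8)
  m2 <- matrix(rpois(200, 5) + 1L, 20, 10,
               dimnames = dimnames(m))
  b2 <- make_bundle(m2); b2$normalized <- b2$counts
  b3 <- b2; b3$normalized <- b2$normalized + 7  # add constant k everywhere
  s2 <- module_score(b2, c("g02", "g07", "g11"), score_params(4, 10, 3))
  s3 <- module_score(b3, c("g02", "g07", "g11"), score_params(4, 10, 3))
  expect_equal(s2, s3, tolerance = 1e-12)

  expect_error(module_score(b2, c("nope1", "nope2")), "nope1")
})

test_that("module_score reproduces the seeded control draw exactly", {
  set.seed(21)
  m <- matrix(rpois(20 * 12, 4), 20, 12,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:12)))
  b <- make_bundle(m); b$normalized <- b$counts
  sig <- c("g03", "g15")
  params <- score_params(n_bins = 2, n_ctrl = 1, rng_seed = 77)
  got <- module_score(b, sig, params)

  # independent recomputation of binning + sampling with the same generator
  X <- as.matrix(b$normalized)
  avg <- rowMeans(X)
  r <- rank(avg, ties.method = "first")
  bins <- as.integer(ceiling(r / (length(avg) / 2)))
  names(bins) <- rownames(X)
  set.seed(77)
  ctrl <- unlist(lapply(sig, function(g) {
    pool <- rownames(X)[bins == bins[[g]]]
    pool[sample.int(length(pool), 1, replace = TRUE)]
  }))
  expected <- colMeans(X[sig, , drop = FALSE]) - colMeans(X[ctrl, , drop = FALSE])
  expect_equal(got, expected, tolerance = 1e-12)

  # bit-reproducible given (data, params, seed)
  expect_identical(got, module_score(b, sig, params))
})

test_that("rank_signature_score: extremal and degenerate cases, oracle match", {
  set.seed(4)
  bulk <- matrix(rnorm(2 * 10, 5), 2, 10,
                 dimnames = list(c("s1", "s2"), paste0("g", 1:10)))
  # set occupying the top |S| ranks of a sample scores maximally
  bulk["s1", ] <- 10:1                          # g1..g3 are the top 3
  sets <- combn(paste0("g", 1:10), 3, simplify = FALSE)
  scores1 <- vapply(sets, function(s)
    rank_signature_score(bulk, s)[["s1"]], numeric(1))
  expect_equal(which.max(scores1), 1L)

  # set == all genes: identical scores across samples
  all_scores <- rank_signature_score(bulk, paste0("g", 1:10))
  expect_equal(all_scores[["s1"]], all_scores[["s2"]], tolerance = 1e-12)

  # constant sample scores 0 with tie flag
  bulk2 <- bulk; bulk2["s2", ] <- 3
  s <- rank_signature_score(bulk2, c("g1", "g2"))
  expect_equal(s[["s2"]], 0)
  expect_true(attr(s, "tie_flag")[2])

  # brute-force running-sum oracle on a 10-gene 2-sample fixture
  alpha <- 0.25
  oracle <- function(x, set_idx) {
    n <- length(x)
    ord <- order(x, decreasing = TRUE)
    run <- 0; acc <- 0
    hits <- which(ord %in% set_idx)
    w <- (n - seq_len(n) + 1)^alpha
    denom <- sum(w[hits])
    for (i in seq_len(n)) {
      run <- run + if (i %in% hits) w[i] / denom else -1 / (n - length(set_idx))
      acc <- acc + run
    }
    acc / n
  }
  got <- rank_signature_score(bulk, c("g2", "g5", "g9"), alpha)
  expect_equal(got[["s1"]], oracle(bulk["s1", ], c(2, 5, 9)), tolerance = 1e-12)
  expect_equal(got[["s2"]], oracle(bulk["s2", ], c(2, 5, 9)), tolerance = 1e-12)
})

test_that("preranked GSEA: hand-computed ES, extremal prefix, antisymmetry", {
  genes <- paste0("g", 1:5)
  res <- preranked_gsea(genes, weights = 5:1, gene_set = c("g1", "g3"),
                        weight_exp = 0, n_perm = 99, rng_seed = 1)
  expect_equal(res$es, 2 / 3, tolerance = 1e-12)   # running sum peaks at g3
  expect_equal(res$leading_edge, c("g1", "g3"))

  top <- preranked_gsea(paste0("g", 1:20), weights = 20:1,
                        gene_set = paste0("g", 1:4), weight_exp = 0,
                        n_perm = 99, rng_seed = 1)
  expect_equal(top$es, 1, tolerance = 1e-12)

  set.seed(11)
  genes2 <- paste0("g", 1:30)
  gs <- sample(genes2, 6)
  fwd <- preranked_gsea(genes2, weights = rep(1, 30), gene_set = gs,
                        weight_exp = 0, n_perm = 99, rng_seed = 2)
  rev_ <- preranked_gsea(rev(genes2), weights = rep(1, 30), gene_set = gs,
                         weight_exp = 0, n_perm = 99, rng_seed = 2)
  expect_equal(fwd$es, -rev_$es, tolerance = 1e-12)

  # brute-force oracle on random <= 10-gene fixtures, weighted
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(6:10, 1)
    hit <- sort(sample(n, 3))
    w <- sort(runif(n, 0.5, 3), decreasing = TRUE)
    got <- preranked_gsea(paste0("g", 1:n), weights = w,
                          gene_set = paste0("g", hit), weight_exp = 1,
                          n_perm = 99, rng_seed = 3)
    expect_equal(got$es, brute_es(n, hit, w, 1), tolerance = 1e-12)
  }
  expect_error(preranked_gsea(genes, gene_set = "absent"), "fewer than 2")
})

test_that("GSEA permutation p-values are uniform under the null", {
  set.seed(300)
  genes <- paste0("g", 1:50)
  ps <- vapply(1:500, function(i) {
    gs <- sample(genes, 5)
    preranked_gsea(sample(genes), weights = rep(1, 50), gene_set = gs,
                   weight_exp = 0, n_perm = 99, rng_seed = i)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("scores are invariant to cell/sample storage order", {
  b <- random_bundle(seed = 13)
  sig <- rownames(b$counts)[1:5]
  perm <- sample(ncol(b$counts))
  b2 <- subset_cells(b, perm)
  s1 <- module_score(b, sig, score_params(rng_seed = 5))
  s2 <- module_score(b2, sig, score_params(rng_seed = 5))
  expect_equal(s1[b2$cell_ids], s2, tolerance = 1e-12)

  bulk <- generate_bulk(6, 40, rng_seed = 9)
  sc <- rank_signature_score(bulk, colnames(bulk)[1:5])
  sc_perm <- rank_signature_score(bulk[c(3, 1, 6, 2, 5, 4), ], colnames(bulk)[1:5])
  expect_equal(sc[names(sc_perm)], sc_perm, tolerance = 1e-12,
               ignore_attr = TRUE)
})
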