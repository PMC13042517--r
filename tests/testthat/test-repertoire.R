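# Clonotype calling, expansion statistics, overlap and clone fate.

test_that("call_clonotypes keeps paired productive chains, UMI tie-break", {
  ct <- call_clonotypes(make_contigs(c("bc1", "bc1"), c("TRA", "TRB"),
                                     c("TGTA", "TGTB")))
  expect_equal(nrow(ct), 1)
  expect_equal(ct$clonotype_id, "TGTA_TGTB")

  # TRB only -> dropped
  expect_equal(nrow(call_clonotypes(make_contigs("bc2", "TRB", "TGTB"))), 0)

  # two TRAs: the higher-UMI chain wins
  tri <- make_contigs(rep("bc3", 3), c("TRA", "TRA", "TRB"),
                      c("AAA", "CCC", "GGG"), umis = c(5L, 9L, 4L))
  ct3 <- call_clonotypes(tri)
  expect_equal(ct3$cdr3a, "CCC")

  # non-productive and non-TR chains never contribute
  mix <- make_contigs(rep("bc4", 3), c("TRA", "TRB", "other"),
                      c("AAA", "TTT", "ZZZ"),
                      productive = c(TRUE, FALSE, TRUE))
  expect_equal(nrow(call_clonotypes(mix)), 0)

  # aa level groups cells whose nt differ but aa agree
  two <- rbind(make_contigs(c("x1", "x1"), c("TRA", "TRB"), c("AAT", "CCT"),
                            cdr3_aa = c("CAF", "CBF")),
               make_contigs(c("x2", "x2"), c("TRA", "TRB"), c("AAC", "CCC"),
                            cdr3_aa = c("CAF", "CBF")))
  expect_equal(length(unique(call_clonotypes(two, "nt")$clonotype_id)), 2)
  expect_equal(length(unique(call_clonotypes(two, "aa")$clonotype_id)), 1)
})

test_that("expansion classes count cells (not clones) within scope", {
  tab <- make_clonotable(rep(c("A", "B", "C"), c(5, 1, 1)))
  ec <- expansion_classes(tab, by = "cluster")
  expect_equal(ec$frac_expanded, 5 / 7, tolerance = 1e-12)
  expect_equal(ec$frac_expanded + ec$frac_small, 1)

  singletons <- make_clonotable(paste0("cl", 1:6))
  expect_equal(expansion_classes(singletons, "cluster")$frac_expanded, 0)
  mono <- make_clonotable(rep("A", 3))
  expect_equal(expansion_classes(mono, "cluster")$frac_expanded, 1)

  # clones are scoped within patient: same id across patients is two clones
  split2 <- make_clonotable(rep("A", 4), patient_id = c("P1", "P1", "P2", "P2"))
  ec2 <- expansion_classes(split2, by = "cluster", size_cut = 2)
  expect_equal(ec2$frac_expanded, 0)                 # two clones of size 2
  pooled <- expansion_classes(split2, by = "cluster", size_cut = 2,
                              clone_scope = NULL)
  expect_equal(pooled$frac_expanded, 1)              # one clone of size 4
})

test_that("expansion index matches the entropy closed form", {
  expect_equal(expansion_index(make_clonotable(c("A", "A", "B", "C"))),
               1 - 1.039721 / log(3), tolerance = 1e-5)
  expect_equal(expansion_index(make_clonotable(paste0("c", 1:8))), 0)
  expect_equal(expansion_index(make_clonotable(rep("A", 10))), 1)
  expect_true(is.na(expansion_index(make_clonotable("A"))))
  # zero iff all clonotype frequencies equal
  expect_equal(expansion_index(make_clonotable(rep(c("A", "B"), each = 4))), 0)
  expect_gt(expansion_index(make_clonotable(c("A", "A", "A", "B"))), 0)
})

test_that("clonotype overlap is symmetric with correct set arithmetic", {
  tab <- make_clonotable(c("x", "y", "z", "y", "z", "w"),
                         cluster = rep(c("A", "B"), each = 3))
  ov <- clonotype_overlap(tab, "cluster")
  expect_equal(ov$shared["A", "B"], 2)
  expect_equal(ov$jaccard["A", "B"], 0.5)
  expect_equal(ov$shared, t(ov$shared))
  expect_equal(diag(ov$jaccard), c(A = 1, B = 1))
  expect_equal(diag(ov$shared), c(A = 3, B = 3))     # own clonotype counts

  disj <- make_clonotable(c("a", "b", "c", "d"), cluster = rep(c("A", "B"), 2))
  expect_equal(clonotype_overlap(disj, "cluster")$jaccard["A", "B"], 0)
  same <- make_clonotable(rep(c("a", "b"), 2), cluster = rep(c("A", "B"), each = 2))
  expect_equal(clonotype_overlap(same, "cluster")$jaccard["A", "B"], 1)
})

test_that("clone fate classification applies the persistence-ratio rule", {
  tab <- make_clonotable(
    c(rep("K1", 4), rep("K2", 4), rep("K3", 4)),
    timepoint = c("PreT", "PreT", "PostT", "PostT",      # ratio 0.5
                  "PreT", "PreT", "PreT", "PostT",       # ratio 0.25
                  "PostT", "PostT", "PostT", "PostT"))   # no baseline
  fates <- classify_clone_fate(tab, fate_params(threshold = 0.3))
  f <- setNames(fates$fate, fates$clonotype_id)
  expect_equal(unname(f[c("K1", "K2", "K3")]),
               c("TCR_Alive", "TCR_Dead", "excluded"))
  expect_equal(fates$ratio[fates$clonotype_id == "K2"], 0.25)

  # without the baseline requirement the late clone is alive
  f2 <- classify_clone_fate(tab, fate_params(require_baseline = FALSE))
  expect_equal(f2$fate[f2$clonotype_id == "K3"], "TCR_Alive")

  expect_error(classify_clone_fate(make_clonotable(c("A", "A"),
                                                   timepoint = "PreT")),
               "no post-treatment")

  # invariant to cell ordering
  shuffled <- tab[sample(nrow(tab)), ]
  expect_equal(classify_clone_fate(shuffled, fate_params())$fate, fates$fate)
})

test_that("fate sensitivity grid yields nested TCR_Alive sets", {
  set.seed(12)
  n_cl <- 40
  pre <- rpois(n_cl, 3) + 1
  post <- rpois(n_cl, 3)
  ids <- sprintf("cl%02d", seq_len(n_cl))
  tab <- make_clonotable(c(rep(ids, pre), rep(ids, post)),
                         timepoint = rep(c("PreT", "PostT"),
                                         c(sum(pre), sum(post))))
  grids <- fate_sensitivity(tab, fate_params(0.3, c(0.4, 0.5, 0.6)))
  alive <- lapply(grids, function(g) g$clonotype_id[g$fate == "TCR_Alive"])
  expect_true(all(alive[["0.6"]] %in% alive[["0.5"]]))
  expect_true(all(alive[["0.5"]] %in% alive[["0.4"]]))
  expect_true(all(alive[["0.4"]] %in% alive[["0.3"]]))

  # boundary case: ratio 0.45 is alive at 0.4 only
  tab2 <- make_clonotable(rep("K", 20),
                          timepoint = rep(c("PreT", "PostT"), c(11, 9)))
  g2 <- fate_sensitivity(tab2, fate_params(0.3, c(0.4, 0.5, 0.6)))
  expect_equal(vapply(g2, function(g) g$fate, character(1)),
               c("0.3" = "TCR_Alive", "0.4" = "TCR_Alive",
                 "0.5" = "TCR_Dead", "0.6" = "TCR_Dead"))
})

test_that("fate-response association reproduces the hand-worked chi-square", {
  cf <- data.frame(
    fate = rep(c("TCR_Alive", "TCR_Dead", "TCR_Alive", "TCR_Dead"),
               c(90, 10, 10, 90)),
    response = rep(c("MPR", "NMPR"), each = 100))
  res <- fate_response_association(cf)
  expect_equal(res$statistic, 128, tolerance = 1e-12)
  expect_equal(res$df, 1)

  balanced <- data.frame(fate = rep(c("TCR_Alive", "TCR_Dead"), 50),
                         response = rep(c("MPR", "NMPR"), each = 50))
  expect_equal(fate_response_association(balanced)$statistic, 0,
               tolerance = 1e-12)
  expect_error(fate_response_association(
    data.frame(fate = "TCR_Alive", response = c("MPR", "NMPR"))),
    "both fates")
})

test_that("every cell belongs to one clonotype; sizes sum to cell count", {
  co <- generate_cohort(cohort_config(rng_seed = 3))
  ct <- call_clonotypes(co$contigs, cell_meta = co$tcr_meta)
  expect_equal(anyDuplicated(ct$cell_id), 0L)
  sizes <- table(paste(ct$patient_id, ct$clonotype_id))
  expect_equal(sum(sizes), nrow(ct))
})
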