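# End-to-end orchestration: QC -> normalize -> differential expression and
# signatures -> Ro/e -> repertoire -> ligand-receptor interactions ->
# survival, over a directory of inputs or an in-memory synthetic cohort,
# producing a machine-readable run report.

#' Assemble a pipeline configuration
#'
#' Either `input_dir` (the on-disk layout of [write_cohort()]) or an
#' in-memory `cohort` must be supplied. Cluster labels are an input: the
#' pipeline does not cluster.
#'
#' @param input_dir Directory holding matrix.mtx + features.tsv +
#'   barcodes.tsv + cell_meta.csv, optional contigs.csv, tcr_meta.csv and
#'   survival.csv.
#' @param cohort A `SyntheticCohort`, used instead of `input_dir`.
#' @param qc,norm,de,score,fate,cutpoint Parameter objects (see
#'   [qc_params()], [norm_params()], [de_params()], [score_params()],
#'   [fate_params()], [cutpoint_params()]).
#' @param signature_cluster Cluster whose marker signature is built and
#'   scored (default "Epi_PRDM1", the synthetic default's malignant state).
#' @param lr_pairs List of `LRPair`s to test; default CD47-SIRPA and
#'   IL1A-IL1R2.
#' @param lr_sender,lr_receivers Sender cluster and receiver clusters for
#'   the interaction tests.
#' @param n_perm Permutations for interaction tests.
#' @param alpha Significance level (default 0.05).
#' @param signature_n Signature size (default 40).
#' @param rng_seed Master seed for every stochastic stage.
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(input_dir = NULL, cohort = NULL,
                            qc = qc_params(), norm = norm_params(),
                            de = de_params(min_pct = 0.25, logfc_threshold = 0.25),
                            score = score_params(),
                            fate = fate_params(),
                            cutpoint = cutpoint_params("median"),
                            signature_cluster = "Epi_PRDM1",
                            lr_pairs = list(lr_pair("CD47_SIRPA", "CD47", "SIRPA"),
                                            lr_pair("IL1A_IL1R2", "IL1A", "IL1R2")),
                            lr_sender = "Epi_PRDM1",
                            lr_receivers = c("Mac_LAM", "Treg"),
                            n_perm = 199, alpha = 0.05, signature_n = 40,
                            rng_seed = 1L) {
  if (is.null(input_dir) && is.null(cohort))
    stop_validation("supply input_dir or cohort")
  structure(list(input_dir = input_dir, cohort = cohort, qc = qc, norm = norm,
                 de = de, score = score, fate = fate, cutpoint = cutpoint,
                 signature_cluster = signature_cluster, lr_pairs = lr_pairs,
                 lr_sender = lr_sender, lr_receivers = lr_receivers,
                 n_perm = n_perm, alpha = alpha, signature_n = signature_n,
                 rng_seed = as.integer(rng_seed)),
            class = "PipelineConfig")
}

#' Run the full pipeline
#'
#' Stages run in order: QC, normalization, differential expression and
#' signature scoring for the configured cluster, Ro/e over crossed
#' tissue-by-response categories, repertoire analysis (skipped with a
#' notice when contigs are absent), ligand-receptor permutation tests, and
#' survival (skipped when no survival table is present). All randomness
#' derives from `config$rng_seed`; rerunning with identical inputs and
#' config reproduces the report exactly.
#'
#' @param config A `PipelineConfig`.
#' @param report_path Optional path to write the report as JSON.
#' @return A list of class `RunReport`.
#' @export
run_pipeline <- function(config, report_path = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  report <- list(seed = config$rng_seed,
                 version = as.character(utils::packageVersion("tmekit")),
                 stages = list())
  note <- function(name, ...) {
    report$stages[[name]] <<- list(...)
    message("[", name, "] ", paste(names(list(...)),
                                   vapply(list(...), function(x)
                                     paste(utils::head(format(x), 1)), character(1)),
                                   sep = "=", collapse = " "))
  }

  # -- load ----------------------------------------------------------------
  if (!is.null(config$cohort)) {
    cohort <- config$cohort
  } else {
    d <- config$input_dir
    cohort <- list(
      bundle = stage("load", read_mtx_bundle(
        file.path(d, "matrix.mtx"), file.path(d, "features.tsv"),
        file.path(d, "barcodes.tsv"), file.path(d, "cell_meta.csv"))),
      contigs = if (file.exists(file.path(d, "contigs.csv")))
        read_contig_csv(file.path(d, "contigs.csv")),
      tcr_meta = if (file.exists(file.path(d, "tcr_meta.csv")))
        utils::read.csv(file.path(d, "tcr_meta.csv"), stringsAsFactors = FALSE),
      survival = if (file.exists(file.path(d, "survival.csv")))
        read_survival_csv(file.path(d, "survival.csv")))
  }
  bundle <- cohort$bundle
  note("input", n_genes = nrow(bundle$counts), n_cells = ncol(bundle$counts))

  # -- qc + normalize ------------------------------------------------------
  bundle <- stage("qc", filter_cells(bundle, config$qc))
  note("qc", n_cells = ncol(bundle$counts),
       params = unlist(unclass(config$qc)))
  bundle <- stage("normalize", normalize_bundle(bundle, config$norm))
  note("normalize", scale_factor = config$norm$scale_factor)

  # -- differential expression + signature ---------------------------------
  cl <- bundle$cell_meta$cluster
  if (config$signature_cluster %in% cl) {
    de <- stage("de", wilcoxon_de(bundle, cl == config$signature_cluster,
                                  cl != config$signature_cluster, config$de))
    sig <- stage("signature", signature_from_de(de, n = config$signature_n))
    scores <- stage("module_score", module_score(bundle, sig, config$score))
    in_mean <- mean(scores[cl == config$signature_cluster])
    out_mean <- mean(scores[cl != config$signature_cluster])
    note("de", n_tested = nrow(de), signature_size = length(sig),
         score_in = in_mean, score_out = out_mean)
    report$signature <- as.character(sig)
    report$signature_score_gap <- in_mean - out_mean
  }

  # -- Ro/e ----------------------------------------------------------------
  tab <- stage("roe", make_contingency(bundle$cell_meta, "cluster",
                                       c("response", "tissue")))
  roe <- stage("roe", ro_e(tab))
  chs <- stage("roe", chi_square_test(tab))
  note("roe", dims = dim(tab), chisq = chs$statistic, p = chs$p_value)
  report$roe <- roe

  # -- repertoire ----------------------------------------------------------
  if (!is.null(cohort$contigs)) {
    ct <- stage("repertoire", call_clonotypes(cohort$contigs,
                                              cell_meta = cohort$tcr_meta))
    fates <- stage("repertoire", classify_clone_fate(ct, config$fate))
    assoc <- stage("repertoire",
                   fate_response_association(attr(fates, "cell_fates")))
    note("repertoire", n_cells = nrow(ct),
         n_alive = sum(fates$fate == "TCR_Alive"),
         n_dead = sum(fates$fate == "TCR_Dead"),
         fate_chisq = assoc$statistic, fate_p = assoc$p_value)
    report$fate_counts <- table(fates$fate)
    report$fate_association <- assoc[c("statistic", "df", "p_value")]
  } else {
    note("repertoire", skipped = "no contigs supplied")
  }

  # -- ligand-receptor interactions ----------------------------------------
  if (length(config$lr_pairs) && config$lr_sender %in% cl) {
    results <- list()
    k <- 0L
    for (pair in config$lr_pairs) for (rcv in config$lr_receivers) {
      if (!rcv %in% cl) next
      k <- k + 1L
      results[[k]] <- stage("interactions", lr_permutation_test(
        bundle, cl, pair, config$lr_sender, rcv, n_perm = config$n_perm,
        rng_seed = sub_seed(config$rng_seed, 100L + k), alpha = config$alpha))
    }
    if (length(results)) {
      sig_counts <- count_significant_pairs(results, config$alpha)
      note("interactions", n_tests = length(results),
           n_significant = sum(sig_counts$n_significant))
      report$interactions <- data.frame(
        pair = vapply(results, `[[`, character(1), "pair"),
        sender = vapply(results, `[[`, character(1), "sender"),
        receiver = vapply(results, `[[`, character(1), "receiver"),
        score = vapply(results, `[[`, numeric(1), "score"),
        p_value = vapply(results, `[[`, numeric(1), "p_value"))
      report$significant_pairs <- sig_counts
    }
  }

  # -- survival ------------------------------------------------------------
  if (!is.null(cohort$survival)) {
    surv <- cohort$survival
    km <- stage("survival", km_estimate(surv))
    report$km_12_36 <- 100 * km_surv_at(km, c(12, 36))
    if (!is.null(surv$group) && length(unique(surv$group)) == 2) {
      lr <- stage("survival", logrank_test(surv))
      cx <- stage("survival", cox_hr(surv))
      note("survival", n = nrow(surv), logrank_p = lr$p_value,
           hr = cx$hr, diverged = cx$diverged)
      report$survival <- list(logrank = lr[c("statistic", "df", "p_value")],
                              cox = cx[c("hr", "ci", "p_value", "diverged")])
    } else {
      note("survival", n = nrow(surv))
    }
  } else {
    note("survival", skipped = "no survival table supplied")
  }

  class(report) <- c("RunReport", "list")
  if (!is.null(report_path))
    jsonlite::write_json(unclass_report(report), report_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

# Flatten matrices/tables for JSON serialization.
unclass_report <- function(report) {
  rapply(unclass(report), function(x) {
    if (is.matrix(x)) as.data.frame(x) else if (is.table(x)) as.list(x) else x
  }, how = "replace")
}
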