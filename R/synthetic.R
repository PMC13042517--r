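# Seeded synthetic-cohort generators. The defaults emulate the study design
# the pipeline targets: 9 patients (5 MPR / 4 NMPR), 26 samples over four
# tissue categories (Normal, Adjacent, pre- and post-treatment tumor),
# negative-binomial counts with cluster-specific markers, planted
# cluster-by-condition enrichments, planted ligand-receptor coexpression,
# power-law clone-size repertoires with response-dependent persistence, and
# two-group exponential survival. Cell counts and the gene universe are
# reduced relative to real data so every stage runs in seconds.

#' Configuration for the synthetic cohort generator
#'
#' @param n_patients Number of patients (default 9).
#' @param responses Response label per patient (default 5 MPR then 4 NMPR).
#' @param cells_per_sample Cells drawn per sample (default 120).
#' @param n_genes Background gene count before markers/receptor genes and
#'   mitochondrial genes are appended (default 360).
#' @param clusters List of cluster specs: `name`, baseline `prop`
#'   (proportions sum to 1), `markers` count, marker `log2fc`, and an
#'   optional `enrich` named vector of fold changes keyed by
#'   `tissue` or `response_tissue` condition (e.g. `c(NMPR_PostT = 3)`).
#' @param marker_log2fc Default marker effect (log2 fold change, default 2).
#' @param dispersion Negative-binomial size parameter (default 2).
#' @param lib_sdlog Log-normal sd of per-cell library size factors.
#' @param lr_plants List of planted ligand-receptor coexpressions:
#'   `ligand`, `receptor`, `sender`, `receiver`, `fold` (default CD47-SIRPA
#'   epithelial-to-macrophage and IL1A-IL1R2 epithelial-to-Treg, 8-fold).
#' @param clone_spec Clone repertoire: `n_clones` per patient, power-law
#'   exponent `alpha`, response-dependent `persistence` probabilities, and
#'   the death-mode resampling rate `dead_rate`.
#' @param survival_spec Two-group exponential survival: per-group `hazard`
#'   (events/month), group sizes `n`, administrative `censor_time` months.
#' @param rng_seed Master seed; all generation derives from it.
#' @return A list of class `CohortConfig`.
#' @export
cohort_config <- function(n_patients = 9,
                          responses = rep(c("MPR", "NMPR"), c(5, 4)),
                          cells_per_sample = 120,
                          n_genes = 360,
                          clusters = NULL,
                          marker_log2fc = 2,
                          dispersion = 2,
                          lib_sdlog = 0.3,
                          lr_plants = NULL,
                          clone_spec = list(n_clones = 60, alpha = 2.5,
                                            persistence = c(MPR = 0.7, NMPR = 0.25),
                                            dead_rate = 0.15),
                          survival_spec = list(hazard = c(MPR = 0.004, NMPR = 0.035),
                                               n = c(MPR = 10, NMPR = 12),
                                               censor_time = 44.4),
                          rng_seed = 1L) {
  if (length(responses) != n_patients)
    stop_validation("responses must have one label per patient")
  clusters <- clusters %||% list(
    list(name = "Tcell",     prop = 0.30, markers = 10),
    list(name = "Treg",      prop = 0.10, markers = 10,
         enrich = c(NMPR_PostT = 3)),
    list(name = "Epi_PRDM1", prop = 0.20, markers = 10),
    list(name = "Mac_LAM",   prop = 0.15, markers = 10),
    list(name = "Bcell",     prop = 0.25, markers = 10))
  props <- vapply(clusters, `[[`, numeric(1), "prop")
  if (abs(sum(props) - 1) > 1e-8)
    stop_validation("cluster proportions must sum to 1")
  if (any(props <= 0)) stop_validation("cluster proportions must be positive")
  lr_plants <- lr_plants %||% list(
    list(ligand = "CD47", receptor = "SIRPA",
         sender = "Epi_PRDM1", receiver = "Mac_LAM", fold = 8),
    list(ligand = "IL1A", receptor = "IL1R2",
         sender = "Epi_PRDM1", receiver = "Treg", fold = 8))
  for (pl in lr_plants) if (pl$fold <= 0) stop_validation("LR plant folds must be > 0")
  if (any(clone_spec$persistence < 0 | clone_spec$persistence > 1))
    stop_validation("persistence probabilities must lie in [0, 1]")
  structure(list(n_patients = n_patients, responses = responses,
                 cells_per_sample = cells_per_sample, n_genes = n_genes,
                 clusters = clusters, marker_log2fc = marker_log2fc,
                 dispersion = dispersion, lib_sdlog = lib_sdlog,
                 lr_plants = lr_plants, clone_spec = clone_spec,
                 survival_spec = survival_spec,
                 rng_seed = as.integer(rng_seed)),
            class = "CohortConfig")
}

# Sample design: every patient contributes PreT and PostT tumor; the first
# four patients also contribute Normal tissue and the last four Adjacent,
# giving 26 samples under the default 9-patient design.
cohort_samples <- function(config) {
  pats <- sprintf("P%02d", seq_len(config$n_patients))
  rows <- list()
  for (i in seq_along(pats)) {
    tis <- c("PreT", "PostT")
    if (i <= 4) tis <- c(tis, "Normal")
    if (i > config$n_patients - 4) tis <- c(tis, "Adjacent")
    for (tt in tis)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = paste(pats[i], tt, sep = "_"), patient_id = pats[i],
        tissue = tt, response = config$responses[i], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Cluster mixing proportions for one sample: baseline proportions times any
# enrichment fold matching the sample's tissue or response_tissue key,
# renormalized to sum to 1.
cluster_props <- function(config, tissue, response) {
  p <- vapply(config$clusters, `[[`, numeric(1), "prop")
  names(p) <- vapply(config$clusters, `[[`, character(1), "name")
  for (cl in config$clusters) {
    en <- cl$enrich
    if (is.null(en)) next
    keys <- c(tissue, paste(response, tissue, sep = "_"))
    hit <- intersect(names(en), keys)
    if (length(hit)) p[cl$name] <- p[cl$name] * prod(en[hit])
  }
  p / sum(p)
}

#' Draw per-cell annotations (no expression) for a synthetic cohort
#'
#' The fast path behind [generate_cohort()]: samples cluster labels per
#' sample from the configured (possibly enriched) mixing proportions.
#' Useful on its own for testing composition statistics at large cell
#' counts.
#'
#' @param config A `CohortConfig`.
#' @param cells_per_sample Override of the configured cells per sample.
#' @return Data frame: `cell_id`, `sample_id`, `patient_id`, `tissue`,
#'   `response`, `cluster`.
#' @export
generate_cell_meta <- function(config, cells_per_sample = config$cells_per_sample) {
  samples <- cohort_samples(config)
  with_seed(sub_seed(config$rng_seed, 1L), {
    metas <- lapply(seq_len(nrow(samples)), function(i) {
      s <- samples[i, ]
      p <- cluster_props(config, s$tissue, s$response)
      cl <- sample(names(p), cells_per_sample, replace = TRUE, prob = p)
      data.frame(cell_id = sprintf("%s_c%04d", s$sample_id, seq_len(cells_per_sample)),
                 sample_id = s$sample_id, patient_id = s$patient_id,
                 tissue = s$tissue, response = s$response, cluster = cl,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, metas)
  })
}

#' Generate a full synthetic cohort
#'
#' Produces (1) an expression bundle with negative-binomial counts,
#' cluster-specific marker genes, planted ligand-receptor coexpression and
#' mitochondrial genes; (2) a contig table plus TCR cell annotations with
#' power-law clone sizes and response-dependent clone persistence; (3) a
#' two-group exponential survival table; and (4) a ground-truth sidecar
#' recording every planted effect. Fully reproducible from
#' `config$rng_seed`.
#'
#' @param config A `CohortConfig`.
#' @return List of class `SyntheticCohort`: `bundle`, `contigs`,
#'   `tcr_meta`, `survival`, `truth`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "CohortConfig"))
  meta <- generate_cell_meta(config)
  n_cells <- nrow(meta)

  cl_names <- vapply(config$clusters, `[[`, character(1), "name")
  n_marker <- vapply(config$clusters, function(cl) cl$markers %||% 10L, numeric(1))
  marker_ids <- split(sprintf("MK%03d", seq_len(sum(n_marker))),
                      rep(seq_along(cl_names), n_marker))
  names(marker_ids) <- cl_names
  lr_genes <- unique(unlist(lapply(config$lr_plants, function(p) c(p$ligand, p$receptor))))
  bg_ids <- sprintf("G%04d", seq_len(config$n_genes))
  mt_ids <- sprintf("MT-%d", 1:10)
  gene_ids <- c(bg_ids, unlist(marker_ids, use.names = FALSE), lr_genes, mt_ids)

  counts <- with_seed(sub_seed(config$rng_seed, 2L), {
    G <- length(gene_ids)
    base_mu <- stats::rlnorm(G, meanlog = log(0.3), sdlog = 1)
    names(base_mu) <- gene_ids
    base_mu[mt_ids] <- 2        # mitochondrial fraction around 4-6%
    base_mu[lr_genes] <- 0.5
    lib <- stats::rlnorm(n_cells, 0, config$lib_sdlog)

    # per-cluster mean vector: baseline, marker boosts, LR plants
    mu_by_cluster <- lapply(cl_names, function(nm) {
      mu <- base_mu
      mu[marker_ids[[nm]]] <- mu[marker_ids[[nm]]] * 2^config$marker_log2fc
      for (pl in config$lr_plants) {
        if (pl$sender == nm) mu[pl$ligand] <- mu[pl$ligand] * pl$fold
        if (pl$receiver == nm) mu[pl$receptor] <- mu[pl$receptor] * pl$fold
      }
      mu
    })
    names(mu_by_cluster) <- cl_names

    m <- matrix(0L, nrow = length(gene_ids), ncol = n_cells,
                dimnames = list(gene_ids, meta$cell_id))
    for (nm in cl_names) {
      idx <- which(meta$cluster == nm)
      if (!length(idx)) next
      mu <- outer(mu_by_cluster[[nm]], lib[idx])
      m[, idx] <- stats::rnbinom(length(mu), size = config$dispersion, mu = mu)
    }
    m
  })
  bundle <- expression_bundle(counts, cell_meta = meta[, -1, drop = FALSE])

  tcr <- generate_repertoire(config)
  surv <- generate_survival(n = config$survival_spec$n,
                            hazard_by_group = config$survival_spec$hazard,
                            censor_time = config$survival_spec$censor_time,
                            rng_seed = sub_seed(config$rng_seed, 4L))

  truth <- list(
    enrichments = lapply(Filter(function(cl) !is.null(cl$enrich), config$clusters),
                         function(cl) list(cluster = cl$name, enrich = as.list(cl$enrich))),
    markers = marker_ids,
    lr_plants = config$lr_plants,
    persistence = as.list(config$clone_spec$persistence),
    hazards = as.list(config$survival_spec$hazard),
    rng_seed = config$rng_seed)

  structure(list(bundle = bundle, contigs = tcr$contigs,
                 tcr_meta = tcr$tcr_meta, survival = surv, truth = truth),
            class = "SyntheticCohort")
}

# Deterministic nucleotide/aa CDR3 codes for a clone index: each decimal
# digit maps to a distinct dinucleotide, so codes are collision-free.
clone_cdr3 <- function(patient, idx, chain) {
  dinuc <- c("AA", "AC", "AG", "AT", "CA", "CC", "CG", "CT", "GA", "GC")
  digits <- utf8ToInt(sprintf("%02d%03d",
                              match(patient, sprintf("P%02d", 1:99)), idx)) - 48L
  code <- paste0(paste(dinuc[digits + 1L], collapse = ""),
                 if (chain == "A") "GG" else "CC")
  list(nt = paste0("TGTGC", code, "TTT"),
       aa = paste0("CA", chain, patient, "x", idx, "F"))
}

# Power-law clone sizes with response-dependent persistence; emits 10x-style
# contig rows (two productive full-length chains per cell) plus TCR cell
# annotations.
generate_repertoire <- function(config) {
  spec <- config$clone_spec
  pats <- sprintf("P%02d", seq_len(config$n_patients))
  with_seed(sub_seed(config$rng_seed, 3L), {
    contig_rows <- list(); meta_rows <- list()
    for (pi in seq_along(pats)) {
      resp <- config$responses[pi]
      p_keep <- spec$persistence[[resp]]
      u <- stats::runif(spec$n_clones)
      sizes <- pmin(30L, floor(u^(-1 / (spec$alpha - 1))))
      persists <- stats::rbinom(spec$n_clones, 1, p_keep) == 1
      for (k in seq_len(spec$n_clones)) {
        n_pre <- sizes[k]
        n_post <- if (persists[k]) 1L + stats::rpois(1, n_pre)
                  else stats::rbinom(1, n_pre, spec$dead_rate)
        if (n_pre + n_post == 0) next
        a <- clone_cdr3(pats[pi], k, "A"); b <- clone_cdr3(pats[pi], k, "B")
        tps <- rep(c("PreT", "PostT"), c(n_pre, n_post))
        ids <- sprintf("%s_tcr%03d_%02d", pats[pi], k, seq_along(tps))
        for (j in seq_along(tps)) {
          contig_rows[[length(contig_rows) + 1]] <- data.frame(
            barcode = ids[j], chain = c("TRA", "TRB"),
            cdr3_nt = c(a$nt, b$nt), cdr3_aa = c(a$aa, b$aa),
            productive = TRUE, full_length = TRUE,
            umis = 1L + stats::rpois(2, 3), stringsAsFactors = FALSE)
        }
        meta_rows[[length(meta_rows) + 1]] <- data.frame(
          cell_id = ids, patient_id = pats[pi], timepoint = tps,
          response = resp,
          cluster = sample(c("CD8_Teff", "CD8_Tex", "CD8_Stem"),
                           length(tps), replace = TRUE),
          stringsAsFactors = FALSE)
      }
    }
    list(contigs = do.call(rbind, contig_rows),
         tcr_meta = do.call(rbind, meta_rows))
  })
}

#' Generate a two-group exponential survival table
#'
#' Event times are exponential with the per-group hazard; follow-up is
#' administratively censored at `censor_time`.
#'
#' @param n Named vector of group sizes.
#' @param hazard_by_group Named vector of hazards (events/month), > 0.
#' @param censor_time Administrative censoring time (months).
#' @param rng_seed Seed.
#' @return A `SurvivalTable` with `group` column.
#' @export
generate_survival <- function(n, hazard_by_group, censor_time = 44.4,
                              rng_seed = 1L) {
  if (any(hazard_by_group <= 0)) stop_validation("hazards must be > 0")
  groups <- names(hazard_by_group)
  stopifnot(!is.null(groups), all(groups %in% names(n)))
  with_seed(rng_seed, {
    rows <- lapply(groups, function(g) {
      t_ev <- stats::rexp(n[[g]], rate = hazard_by_group[[g]])
      data.frame(group = g, time = pmin(t_ev, censor_time),
                 event = as.numeric(t_ev <= censor_time),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    survival_table(sprintf("S%03d", seq_len(nrow(df))), df$time, df$event,
                   group = df$group)
  })
}

#' Generate a bulk expression cohort with an optional planted signature
#'
#' Log-normal samples x genes expression; designated samples receive an
#' additive shift on the signature genes.
#'
#' @param n_samples,n_genes Matrix dimensions.
#' @param plant Optional list: `genes` (ids or count), `samples` (ids or
#'   count of "high" samples) and `shift` (added to log-scale expression).
#' @param rng_seed Seed.
#' @return Samples x genes matrix; attributes `plant_genes`,
#'   `plant_samples` record the planted effect.
#' @export
generate_bulk <- function(n_samples = 50, n_genes = 200, plant = NULL,
                          rng_seed = 1L) {
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  with_seed(rng_seed, {
    m <- matrix(stats::rnorm(n_samples * n_genes, mean = 6, sd = 1.5),
                n_samples, n_genes, dimnames = list(sample_ids, gene_ids))
    pg <- character(0); ps <- character(0)
    if (!is.null(plant)) {
      pg <- if (is.numeric(plant$genes)) gene_ids[seq_len(plant$genes)] else plant$genes
      ps <- if (is.numeric(plant$samples)) sample_ids[seq_len(plant$samples)] else plant$samples
      m[ps, pg] <- m[ps, pg] + (plant$shift %||% 2)
    }
    attr(m, "plant_genes") <- pg
    attr(m, "plant_samples") <- ps
    m
  })
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Writes the expression bundle (matrix.mtx, features.tsv, barcodes.tsv,
#' cell_meta.csv), contigs.csv, tcr_meta.csv, survival.csv and a
#' truth.json sidecar of planted effects.
#'
#' @param cohort A `SyntheticCohort` from [generate_cohort()].
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mtx_bundle(cohort$bundle, dir)
  contigs <- cohort$contigs
  names(contigs)[names(contigs) == "cdr3_aa"] <- "cdr3"   # 10x header dialect
  utils::write.csv(contigs, file.path(dir, "contigs.csv"), row.names = FALSE)
  utils::write.csv(cohort$tcr_meta, file.path(dir, "tcr_meta.csv"), row.names = FALSE)
  write_survival_csv(cohort$survival, file.path(dir, "survival.csv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
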