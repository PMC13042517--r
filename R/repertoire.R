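# TCR repertoire analysis: clonotype calling from paired-chain contigs,
# clone-size expansion statistics, cross-phenotype clonotype overlap and
# treatment-persistence (clone fate) classification.

#' Call paired-chain clonotypes from contig records
#'
#' Keeps cells carrying at least one productive, full-length TRA and one
#' productive, full-length TRB. When a cell has several chains of one type,
#' the highest-UMI chain wins (ties broken by lexicographically smaller
#' CDR3, for determinism). The clonotype identifier is the (cdr3a, cdr3b)
#' pair at the chosen sequence level; cells sharing it belong to one clone.
#'
#' @param contigs Data frame from [read_contig_csv()].
#' @param level Sequence level defining clonotype identity: `"nt"`
#'   (nucleotide, the stricter default) or `"aa"`.
#' @param cell_meta Optional per-cell annotation joined on `cell_id`
#'   (columns such as cluster, patient_id, timepoint/tissue, response).
#' @return Data frame of class `ClonotypeTable`, one row per retained cell:
#'   `cell_id`, `clonotype_id`, `cdr3a`, `cdr3b` plus any joined metadata.
#'   An empty result is valid.
#' @export
call_clonotypes <- function(contigs, level = c("nt", "aa"), cell_meta = NULL) {
  level <- match.arg(level)
  ok <- contigs$productive & contigs$full_length & contigs$chain %in% c("TRA", "TRB")
  contigs <- contigs[ok, , drop = FALSE]
  seq_col <- if (level == "nt") "cdr3_nt" else "cdr3_aa"

  pick <- function(df) {
    df <- df[order(-df$umis, df[[seq_col]]), , drop = FALSE]
    df[[seq_col]][1]
  }
  out <- data.frame(cell_id = character(), clonotype_id = character(),
                    cdr3a = character(), cdr3b = character(),
                    stringsAsFactors = FALSE)
  if (nrow(contigs)) {
    sp <- split(contigs, contigs$barcode)
    rows <- lapply(names(sp), function(bc) {
      df <- sp[[bc]]
      a <- df[df$chain == "TRA", , drop = FALSE]
      b <- df[df$chain == "TRB", , drop = FALSE]
      if (!nrow(a) || !nrow(b)) return(NULL)
      data.frame(cell_id = bc, cdr3a = pick(a), cdr3b = pick(b),
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    if (!is.null(rows)) {
      rows$clonotype_id <- paste(rows$cdr3a, rows$cdr3b, sep = "_")
      out <- rows[, c("cell_id", "clonotype_id", "cdr3a", "cdr3b")]
    }
  }
  if (!is.null(cell_meta) && nrow(out)) {
    key <- cell_meta$cell_id %||% rownames(cell_meta)
    idx <- match(out$cell_id, key)
    extra <- cell_meta[idx, setdiff(names(cell_meta), c("cell_id", names(out))),
                       drop = FALSE]
    out <- cbind(out, extra)
  }
  rownames(out) <- NULL
  class(out) <- c("ClonotypeTable", "data.frame")
  out
}

# Clone sizes computed within the grouping scope (default: within patient,
# since TCR sharing across individuals is biologically exceptional).
clone_sizes <- function(table, scope = "patient_id") {
  key <- if (!is.null(scope) && all(scope %in% names(table)))
    do.call(paste, c(table[scope], list(table$clonotype_id), sep = "|"))
  else table$clonotype_id
  as.vector(table(key)[match(key, names(table(key)))])
}

#' Fractions of cells in expanded vs small clones, per group
#'
#' Clone size is the number of cells sharing a clonotype within the clone
#' scope (default: within patient); expanded clones are those with more
#' than `size_cut` cells. Fractions are of cells, not clones, and sum to 1
#' per group.
#'
#' @param table A `ClonotypeTable`.
#' @param by Grouping column(s), e.g. `c("cluster", "response")`.
#' @param size_cut Clone-size threshold (default 2: expanded means n > 2).
#' @param clone_scope Column(s) within which clone sizes are counted;
#'   `NULL` pools all cells.
#' @return Data frame with the grouping keys, `n_cells`,
#'   `frac_expanded` and `frac_small`.
#' @export
expansion_classes <- function(table, by = "cluster", size_cut = 2,
                              clone_scope = "patient_id") {
  if (!nrow(table)) stop_validation("empty clonotype table")
  sizes <- clone_sizes(table, clone_scope)
  expanded <- sizes > size_cut
  key <- do.call(paste, c(table[by], sep = "_"))
  agg <- lapply(split(seq_len(nrow(table)), key), function(i)
    c(n_cells = length(i), frac_expanded = mean(expanded[i])))
  out <- data.frame(group = names(agg),
                    n_cells = vapply(agg, `[[`, numeric(1), "n_cells"),
                    frac_expanded = vapply(agg, `[[`, numeric(1), "frac_expanded"),
                    stringsAsFactors = FALSE)
  out$frac_small <- 1 - out$frac_expanded
  rownames(out) <- NULL
  out
}

#' Clonal expansion index of a cell group
#'
#' `1 - H / ln(C)` where `H` is the Shannon entropy (nats) of clonotype
#' frequencies in the group and `C` the number of distinct clonotypes:
#' 0 for a perfectly even repertoire, 1 for a monoclonal one. A single
#' clonotype gives 1; groups of fewer than 2 cells give `NA`.
#'
#' @param table A `ClonotypeTable` (or its subset for one group).
#' @param group Optional logical/index mask selecting the group's rows.
#' @return Scalar in \[0, 1\] or `NA`.
#' @export
expansion_index <- function(table, group = NULL) {
  rows <- if (is.null(group)) table else table[group, , drop = FALSE]
  if (nrow(rows) < 2) return(NA_real_)
  f <- table(rows$clonotype_id)
  p <- as.numeric(f) / sum(f)
  if (length(p) == 1L) return(1)
  H <- -sum(p * log(p))
  1 - H / log(length(p))
}

#' Pairwise clonotype overlap between phenotypes
#'
#' For every pair of phenotype groups, counts shared clonotypes and the
#' Jaccard index of their clonotype sets.
#'
#' @param table A `ClonotypeTable`.
#' @param phenotype_key Column defining the phenotypes (default `cluster`).
#' @return List of two symmetric matrices, `shared` and `jaccard`; the
#'   diagonal carries each phenotype's own clonotype count and 1.
#' @export
clonotype_overlap <- function(table, phenotype_key = "cluster") {
  sets <- lapply(split(table$clonotype_id, table[[phenotype_key]]), unique)
  if (length(sets) < 2) stop_validation("need >= 2 phenotypes for overlap")
  k <- length(sets)
  shared <- matrix(0, k, k, dimnames = list(names(sets), names(sets)))
  jac <- shared
  for (i in seq_len(k)) for (j in seq_len(k)) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    uni <- length(union(sets[[i]], sets[[j]]))
    shared[i, j] <- inter
    jac[i, j] <- if (uni) inter / uni else 0
  }
  list(shared = shared, jaccard = jac)
}

#' Clone-fate classification parameters
#'
#' @param threshold Post-treatment share above which a clone is called
#'   persisting (default 0.3, strict inequality).
#' @param sensitivity_grid Extra thresholds for robustness analysis
#'   (default 0.4, 0.5, 0.6).
#' @param require_baseline Exclude clones absent before treatment (default
#'   TRUE: fate is about persistence from baseline).
#' @param frequency_mode Compute the ratio from compartment-normalized
#'   frequencies instead of raw cell counts (default FALSE).
#' @return A list of class `FateParams`.
#' @export
fate_params <- function(threshold = 0.3, sensitivity_grid = c(0.4, 0.5, 0.6),
                        require_baseline = TRUE, frequency_mode = FALSE) {
  if (any(c(threshold, sensitivity_grid) <= 0 | c(threshold, sensitivity_grid) >= 1))
    stop_validation("fate thresholds must lie in (0, 1)")
  structure(list(threshold = threshold, sensitivity_grid = sensitivity_grid,
                 require_baseline = require_baseline,
                 frequency_mode = frequency_mode), class = "FateParams")
}

#' Classify clone fate from pre/post-treatment cell counts
#'
#' Within each patient, every clonotype's persistence ratio is
#' `n_post / (n_pre + n_post)` (or the frequency-normalized analogue when
#' `frequency_mode`). Clones with ratio strictly above the threshold are
#' `TCR_Alive`, the rest `TCR_Dead`; clones unseen at baseline are
#' `excluded` when `require_baseline`.
#'
#' @param table A `ClonotypeTable` with `timepoint` (PreT/PostT) and
#'   `patient_id` columns.
#' @param params A `FateParams` object.
#' @param threshold Override of `params$threshold`.
#' @return Data frame with one row per (patient, clonotype): `patient_id`,
#'   `clonotype_id`, `n_pre`, `n_post`, `ratio`, `fate`; attribute
#'   `cell_fates` maps each cell to its clone's fate.
#' @export
classify_clone_fate <- function(table, params = fate_params(),
                                threshold = params$threshold) {
  stopifnot(inherits(params, "FateParams"))
  tp <- table$timepoint
  if (!any(tp == "PostT", na.rm = TRUE))
    stop_validation("no post-treatment cells; clone fate undefined")
  rows <- table[tp %in% c("PreT", "PostT"), , drop = FALSE]
  key <- paste(rows$patient_id, rows$clonotype_id, sep = "|")
  pre <- tapply(rows$timepoint == "PreT", key, sum)
  post <- tapply(rows$timepoint == "PostT", key, sum)
  ids <- sort(names(pre))
  n_pre <- as.numeric(pre[ids]); n_post <- as.numeric(post[ids])

  if (params$frequency_mode) {
    pat <- sub("\\|.*$", "", ids)
    pre_tot <- tapply(rows$timepoint == "PreT", rows$patient_id, sum)
    post_tot <- tapply(rows$timepoint == "PostT", rows$patient_id, sum)
    f_pre <- n_pre / pmax(1, as.numeric(pre_tot[pat]))
    f_post <- n_post / pmax(1, as.numeric(post_tot[pat]))
    ratio <- ifelse(f_pre + f_post > 0, f_post / (f_pre + f_post), NA_real_)
  } else {
    ratio <- n_post / (n_pre + n_post)
  }
  fate <- ifelse(ratio > threshold, "TCR_Alive", "TCR_Dead")
  if (params$require_baseline) fate[n_pre == 0] <- "excluded"

  out <- data.frame(patient_id = sub("\\|.*$", "", ids),
                    clonotype_id = sub("^[^|]*\\|", "", ids),
                    n_pre = n_pre, n_post = n_post, ratio = ratio,
                    fate = fate, stringsAsFactors = FALSE)
  cf <- out$fate[match(key, ids)]
  cell_fates <- data.frame(cell_id = rows$cell_id, fate = cf,
                           stringsAsFactors = FALSE)
  if (!is.null(rows$response)) cell_fates$response <- rows$response
  attr(out, "cell_fates") <- cell_fates
  out
}

#' Clone fate at every threshold of the sensitivity grid
#'
#' @param table A `ClonotypeTable`.
#' @param params A `FateParams` object; the grid is
#'   `c(threshold, sensitivity_grid)`.
#' @return Named list of [classify_clone_fate()] results, one per threshold.
#' @export
fate_sensitivity <- function(table, params = fate_params()) {
  grid <- c(params$threshold, params$sensitivity_grid)
  out <- lapply(grid, function(th) classify_clone_fate(table, params, threshold = th))
  names(out) <- format(grid)
  out
}

#' Association between clone fate and therapy response
#'
#' Builds the 2x2 cell-count table of fate (TCR_Alive/TCR_Dead) against
#' response (MPR/NMPR), excluding `excluded` clones, and applies the raw
#' Pearson chi-square test.
#'
#' @param cell_fates Data frame with `fate` and `response` per cell (the
#'   `cell_fates` attribute of [classify_clone_fate()]).
#' @return List with the 2x2 `table` plus `statistic`, `df`, `p_value`.
#' @export
fate_response_association <- function(cell_fates) {
  keep <- cell_fates$fate %in% c("TCR_Alive", "TCR_Dead") &
    cell_fates$response %in% c("MPR", "NMPR")
  tab <- table(factor(cell_fates$fate[keep], c("TCR_Alive", "TCR_Dead")),
               factor(cell_fates$response[keep], c("MPR", "NMPR")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_validation("both fates and both response groups must be present")
  ct <- chi_square_test(contingency_table(unclass(tab)))
  c(list(table = unclass(tab)), ct)
}
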