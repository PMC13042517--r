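#' ExpressionBundle: counts, normalized expression and per-cell annotation
#'
#' The pipeline's central container. Holds a genes x cells integer count
#' matrix (sparse `dgCMatrix`), an optional normalized matrix of the same
#' shape (filled lazily by [normalize_bundle()]), and a per-cell annotation
#' data frame with the cohort design labels: `sample_id`, `patient_id`,
#' `tissue` (Normal / Adjacent / PreT / PostT), `response` (MPR / NMPR / NA),
#' `cluster`, plus QC statistics `mito_fraction` and `n_genes_detected`.
#'
#' @param counts Non-negative integer matrix, genes x cells. Row names are
#'   gene ids, column names cell barcodes; both must be unique.
#' @param cell_meta Data frame with one row per cell, in column order of
#'   `counts`. Missing annotation columns are filled with `NA`; QC columns
#'   are computed from `counts` when absent (see `mito_prefix`).
#' @param gene_symbols Optional display names parallel to rows of `counts`;
#'   duplicates allowed (ids, not symbols, carry identity).
#' @param normalized Optional normalized matrix, same dimensions as `counts`.
#' @param mito_prefix Prefix on the gene symbol (falling back to the id)
#'   marking mitochondrial genes; used to compute `mito_fraction`.
#' @return An object of class `ExpressionBundle`.
#' @export
expression_bundle <- function(counts, cell_meta = NULL, gene_symbols = NULL,
                              normalized = NULL, mito_prefix = "MT-") {
  counts <- as_dgc(counts)
  cell_ids <- colnames(counts) %||% character(0)   # Matrix drops empty dimnames
  if (is.null(rownames(counts)) || (ncol(counts) > 0L && !length(cell_ids)))
    stop_validation("counts must have gene ids as rownames and cell ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop_validation("duplicate gene ids: ",
                    paste(utils::head(unique(rownames(counts)[duplicated(rownames(counts))]), 3), collapse = ", "))
  if (anyDuplicated(cell_ids))
    stop_validation("duplicate cell barcodes: ",
                    paste(utils::head(unique(cell_ids[duplicated(cell_ids)]), 3), collapse = ", "))
  if (any(counts@x < 0)) stop_validation("counts must be non-negative")
  if (any(counts@x != round(counts@x))) stop_validation("counts must be integer-valued")

  if (is.null(gene_symbols)) gene_symbols <- rownames(counts)
  if (length(gene_symbols) != nrow(counts))
    stop_validation("gene_symbols length does not match number of genes")

  meta <- as.data.frame(cell_meta %||% data.frame(row.names = cell_ids))
  if (nrow(meta) == 0L && ncol(counts) > 0L) meta <- data.frame(row.names = colnames(counts))
  if (nrow(meta) != ncol(counts))
    stop_validation("cell_meta has ", nrow(meta), " rows but counts has ", ncol(counts), " cells")
  for (col in c("sample_id", "patient_id", "tissue", "response", "cluster")) {
    if (is.null(meta[[col]])) meta[[col]] <- rep(NA_character_, nrow(meta))
    meta[[col]] <- as.character(meta[[col]])
  }
  bad_tis <- setdiff(stats::na.omit(unique(meta$tissue)), c("Normal", "Adjacent", "PreT", "PostT"))
  if (length(bad_tis)) stop_validation("unknown tissue label(s): ", paste(bad_tis, collapse = ", "))
  bad_rsp <- setdiff(stats::na.omit(unique(meta$response)), c("MPR", "NMPR"))
  if (length(bad_rsp)) stop_validation("unknown response label(s): ", paste(bad_rsp, collapse = ", "))

  mito <- startsWith(gene_symbols, mito_prefix) | startsWith(rownames(counts), mito_prefix)
  totals <- Matrix::colSums(counts)
  if (is.null(meta$n_genes_detected) || anyNA(meta$n_genes_detected))
    meta$n_genes_detected <- Matrix::colSums(counts > 0)
  if (is.null(meta$mito_fraction) || anyNA(meta$mito_fraction)) {
    mt <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE]) else rep(0, ncol(counts))
    meta$mito_fraction <- ifelse(totals > 0, mt / totals, 0)
  }
  if (any(meta$mito_fraction < 0 | meta$mito_fraction > 1))
    stop_validation("mito_fraction must lie in [0, 1]")
  rownames(meta) <- cell_ids

  if (!is.null(normalized)) {
    normalized <- as_dgc(normalized)
    if (!identical(dim(normalized), dim(counts)))
      stop_validation("normalized matrix shape differs from counts")
    dimnames(normalized) <- dimnames(counts)
  }

  structure(list(counts = counts, normalized = normalized,
                 gene_ids = rownames(counts), gene_symbols = gene_symbols,
                 cell_ids = cell_ids, cell_meta = meta,
                 mito_prefix = mito_prefix),
            class = "ExpressionBundle")
}

#' @export
dim.ExpressionBundle <- function(x) dim(x$counts)

#' @export
print.ExpressionBundle <- function(x, ...) {
  cat("ExpressionBundle:", nrow(x$counts), "genes x", ncol(x$counts), "cells\n")
  cat("  normalized:", if (is.null(x$normalized)) "absent" else "present", "\n")
  tt <- table(x$cell_meta$tissue, useNA = "no")
  if (length(tt)) cat("  tissues:", paste(names(tt), tt, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Subset an ExpressionBundle by cells (and optionally genes)
#'
#' @param bundle An `ExpressionBundle`.
#' @param cells Logical mask, indices or cell ids.
#' @param genes Optional gene selector (all genes kept by default: QC never
#'   removes genes).
#' @return A new `ExpressionBundle`; cell order is preserved.
#' @export
subset_cells <- function(bundle, cells, genes = NULL) {
  stopifnot(inherits(bundle, "ExpressionBundle"))
  if (is.logical(cells)) cells <- which(cells)
  if (is.character(cells)) cells <- match(cells, bundle$cell_ids)
  genes <- genes %||% seq_len(nrow(bundle$counts))
  expression_bundle(bundle$counts[genes, cells, drop = FALSE],
                    cell_meta = bundle$cell_meta[cells, , drop = FALSE],
                    gene_symbols = bundle$gene_symbols[genes],
                    normalized = if (!is.null(bundle$normalized)) bundle$normalized[genes, cells, drop = FALSE],
                    mito_prefix = bundle$mito_prefix)
}
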