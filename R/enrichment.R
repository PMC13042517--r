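# Observed-over-expected (Ro/e) tissue/response preference and Pearson
# chi-square tests on cell-subtype x category contingency tables.

#' Build a contingency table of cluster x category cell counts
#'
#' @param cell_meta Per-cell annotation data frame (e.g. `bundle$cell_meta`).
#' @param row_key Column giving the row category (typically `cluster`).
#' @param col_key Column(s) giving the column category; several columns are
#'   crossed with `_` (e.g. `c("tissue", "response")` for the joint
#'   tissue-by-response layout, the default downstream convention).
#' @param drop_na Drop cells with `NA` in any key (default TRUE).
#' @return An integer matrix of class `ContingencyTable`.
#' @export
make_contingency <- function(cell_meta, row_key = "cluster", col_key = "tissue",
                             drop_na = TRUE) {
  rows <- as.character(cell_meta[[row_key]])
  cols <- if (length(col_key) == 1L) as.character(cell_meta[[col_key]])
          else do.call(paste, c(lapply(col_key, function(k) as.character(cell_meta[[k]])),
                                sep = "_"))
  keep <- if (drop_na) !is.na(rows) & !is.na(cols) &
            Reduce(`&`, lapply(col_key, function(k) !is.na(cell_meta[[k]])))
          else rep(TRUE, length(rows))
  tab <- table(rows[keep], cols[keep])
  contingency_table(unclass(tab))
}

#' Validate a counts matrix as a ContingencyTable
#' @param counts Non-negative integer matrix with row/column names.
#' @return The matrix with class `ContingencyTable`.
#' @export
contingency_table <- function(counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(counts < 0) || any(counts != round(counts)))
    stop_validation("contingency counts must be non-negative integers")
  if (sum(counts) <= 0) stop_validation("contingency table has zero grand total")
  if (is.null(rownames(counts))) rownames(counts) <- paste0("r", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("c", seq_len(ncol(counts)))
  structure(counts, class = c("ContingencyTable", "matrix"))
}

# Expected counts under independence: E[i,j] = rowsum_i * colsum_j / N.
expected_counts <- function(tab) {
  outer(rowSums(tab), colSums(tab)) / sum(tab)
}

#' Ro/e: observed over expected cell counts
#'
#' `Ro/e[i,j] = O[i,j] / E[i,j]`, with expectations from the chi-square
#' independence model. Values above 1 flag a preference of subtype i for
#' category j. Rows or columns with zero totals are an error (an `NA` entry
#' is reported instead of 0 when a row empties after upstream filtering but
#' its label is retained via `keep_empty`).
#'
#' @param tab A `ContingencyTable` (or coercible matrix).
#' @param keep_empty If TRUE, all-zero rows yield `NA` entries instead of
#'   erroring.
#' @return Numeric matrix of Ro/e values, same shape and dimnames.
#' @export
ro_e <- function(tab, keep_empty = FALSE) {
  tab <- contingency_table(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(cs == 0))
    stop_validation("zero column total for: ",
                    paste(colnames(tab)[cs == 0], collapse = ", "))
  if (any(rs == 0) && !keep_empty)
    stop_validation("zero row total for: ",
                    paste(rownames(tab)[rs == 0], collapse = ", "))
  E <- expected_counts(tab)
  out <- unclass(tab) / E
  if (keep_empty && any(rs == 0)) out[rs == 0, ] <- NA_real_
  out
}

#' Pearson chi-square test of independence
#'
#' Raw Pearson statistic `sum((O-E)^2 / E)` without continuity correction
#' (matching the Ro/e expectation model); a Yates-corrected variant is
#' available for 2x2 tables via `correct = TRUE`.
#'
#' @param tab A `ContingencyTable` with >= 2 rows and >= 2 columns.
#' @param correct Apply the Yates continuity correction (2x2 only).
#' @return List with `statistic`, `df`, `p_value`, and logical
#'   `low_expected` flagging any expected count below 5.
#' @export
chi_square_test <- function(tab, correct = FALSE) {
  tab <- contingency_table(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop_validation("chi-square needs at least a 2x2 table")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop_validation("zero row/column total: ",
                    paste(c(rownames(tab)[rs == 0], colnames(tab)[cs == 0]), collapse = ", "))
  ct <- suppressWarnings(stats::chisq.test(unclass(tab), correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), low_expected = any(ct$expected < 5))
}
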