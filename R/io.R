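# Readers and writers for the plain-text formats the pipeline touches:
# Matrix Market counts with features/barcodes TSVs, 10x-style filtered contig
# annotation CSVs, GMT gene-set files and survival CSVs. All readers validate
# against the container invariants rather than silently coercing.

#' Read a Matrix Market count matrix with features/barcodes into a bundle
#'
#' Follows the 10x Genomics on-disk layout: an integer-valued `.mtx` matrix,
#' a features TSV whose first column is the unique gene id and second (if
#' present) the display symbol, and a barcodes TSV of cell ids. An optional
#' per-cell metadata CSV is joined on barcode after stripping the 10x `-1`
#' style suffix (configurable).
#'
#' @param matrix_path Path to the `.mtx` file (genes x cells).
#' @param features_path Path to the features/genes TSV.
#' @param barcodes_path Path to the barcodes TSV.
#' @param meta_path Optional path to a per-cell metadata CSV keyed by a
#'   `barcode` column.
#' @param strip_suffix Regular expression removed from barcodes before the
#'   metadata join (default the 10x `-<digit>` suffix); `NULL` to disable.
#' @param permissive If `TRUE`, cells present in the matrix but missing from
#'   the metadata get `NA` annotations; if `FALSE` (default) that is an error.
#' @return An [expression_bundle()].
#' @export
read_mtx_bundle <- function(matrix_path, features_path, barcodes_path,
                            meta_path = NULL, strip_suffix = "-\\d+$",
                            permissive = FALSE) {
  m <- Matrix::readMM(matrix_path)
  if (!methods::is(m, "nMatrix") && any(m@x != round(m@x)))
    stop_format("matrix is not integer-valued: ", matrix_path)
  feats <- utils::read.delim(features_path, header = FALSE,
                             stringsAsFactors = FALSE, colClasses = "character")
  bcs <- utils::read.delim(barcodes_path, header = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")[[1]]
  if (nrow(feats) != nrow(m))
    stop_format("feature count (", nrow(feats), ") does not match matrix rows (",
                nrow(m), "): ", features_path)
  if (length(bcs) != ncol(m))
    stop_format("barcode count (", length(bcs), ") does not match matrix columns (",
                ncol(m), "): ", barcodes_path)
  if (anyDuplicated(bcs))
    stop_validation("duplicated barcode in ", barcodes_path, ": ",
                    bcs[duplicated(bcs)][1])
  if (anyDuplicated(feats[[1]]))
    stop_validation("duplicated feature id in ", features_path, ": ",
                    feats[[1]][duplicated(feats[[1]])][1])
  keys <- if (is.null(strip_suffix)) bcs else sub(strip_suffix, "", bcs)
  rownames(m) <- feats[[1]]
  colnames(m) <- bcs

  meta <- NULL
  if (!is.null(meta_path)) {
    md <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    if (is.null(md$barcode)) stop_format("metadata lacks a 'barcode' column: ", meta_path)
    mkeys <- if (is.null(strip_suffix)) md$barcode else sub(strip_suffix, "", md$barcode)
    if (anyDuplicated(mkeys))
      stop_validation("duplicated barcode in metadata: ", mkeys[duplicated(mkeys)][1])
    idx <- match(keys, mkeys)
    if (anyNA(idx) && !permissive)
      stop_validation(sum(is.na(idx)), " matrix barcode(s) absent from metadata ",
                      "(use permissive = TRUE to keep them with NA annotations)")
    meta <- md[idx, setdiff(names(md), "barcode"), drop = FALSE]
    rownames(meta) <- bcs
  }
  symbols <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  expression_bundle(m, cell_meta = meta, gene_symbols = symbols)
}

#' Write an ExpressionBundle as Matrix Market + TSV + metadata CSV
#'
#' @param bundle An `ExpressionBundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (matrix/features/barcodes/meta).
#' @export
write_mtx_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ExpressionBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c(matrix = "matrix.mtx", features = "features.tsv",
                            barcodes = "barcodes.tsv", meta = "cell_meta.csv"))
  names(paths) <- c("matrix", "features", "barcodes", "meta")
  Matrix::writeMM(bundle$counts, paths[["matrix"]])
  utils::write.table(data.frame(bundle$gene_ids, bundle$gene_symbols),
                     paths[["features"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(bundle$cell_ids, paths[["barcodes"]])
  meta <- cbind(barcode = bundle$cell_ids, bundle$cell_meta)
  utils::write.csv(meta, paths[["meta"]], row.names = FALSE)
  invisible(paths)
}

#' Read a 10x-style filtered contig annotation CSV
#'
#' Mandatory columns (names configurable through `columns`): barcode, chain,
#' nucleotide and amino-acid CDR3, productivity, full-length flag and UMI
#' count. Chains other than TRA/TRB are retained but relabelled `other`;
#' boolean columns accept True/true/TRUE (and False variants).
#'
#' @param path CSV path.
#' @param columns Named character vector mapping the canonical names
#'   (`barcode`, `chain`, `cdr3_nt`, `cdr3_aa`, `productive`, `full_length`,
#'   `umis`) to the file's header names.
#' @return A data frame of contig records, one row per chain.
#' @export
read_contig_csv <- function(path,
                            columns = c(barcode = "barcode", chain = "chain",
                                        cdr3_nt = "cdr3_nt", cdr3_aa = "cdr3",
                                        productive = "productive",
                                        full_length = "full_length",
                                        umis = "umis")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(unname(columns), names(df))
  if (length(missing))
    stop_format("contig CSV missing column(s): ", paste(missing, collapse = ", "))
  parse_bool <- function(x) {
    if (is.logical(x)) return(x)
    tolower(as.character(x)) %in% c("true", "t", "1")
  }
  out <- data.frame(
    barcode = as.character(df[[columns[["barcode"]]]]),
    chain = as.character(df[[columns[["chain"]]]]),
    cdr3_nt = as.character(df[[columns[["cdr3_nt"]]]]),
    cdr3_aa = as.character(df[[columns[["cdr3_aa"]]]]),
    productive = parse_bool(df[[columns[["productive"]]]]),
    full_length = parse_bool(df[[columns[["full_length"]]]]),
    umis = as.integer(df[[columns[["umis"]]]]),
    stringsAsFactors = FALSE)
  if (any(out$umis < 0, na.rm = TRUE)) stop_validation("negative UMI count in ", path)
  out$chain[!out$chain %in% c("TRA", "TRB")] <- "other"
  out
}

#' Read a GMT gene-set file
#'
#' Each line is `set-name<TAB>description<TAB>gene1<TAB>gene2...`. Empty sets
#' and within-set duplicate gene ids are rejected.
#'
#' @param path GMT path.
#' @return A named list of character vectors (a gene-set collection).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop_format("malformed GMT line ", i, ": expected name, description and >= 1 gene")
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop_format("empty gene set on GMT line ", i)
    if (anyDuplicated(genes))
      stop_validation("duplicate gene within set '", parts[1], "' (GMT line ", i, ")")
    sets[[parts[1]]] <- genes
  }
  sets
}

#' Write a gene-set collection as GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(length(names(sets)) == length(sets))
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1)), path)
  invisible(path)
}

#' Read a survival CSV into a validated survival table
#'
#' Requires `subject_id`, `time` (positive, months) and `event` (0/1)
#' columns; optional `group` and `score` columns are carried through.
#'
#' @param path CSV path.
#' @return A data frame of class `SurvivalTable`.
#' @export
read_survival_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("subject_id", "time", "event"), names(df))
  if (length(missing))
    stop_format("survival CSV missing column(s): ", paste(missing, collapse = ", "))
  survival_table(df$subject_id, df$time, df$event,
                 group = df$group, score = df$score)
}

#' Construct a validated survival table
#'
#' @param subject_id Unique subject identifiers.
#' @param time Positive follow-up times (months).
#' @param event Event indicator, 0 = censored, 1 = event.
#' @param group Optional group label per subject.
#' @param score Optional numeric covariate score per subject.
#' @return A data frame of class `SurvivalTable`.
#' @export
survival_table <- function(subject_id, time, event, group = NULL, score = NULL) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (any(!is.finite(time)) || any(time <= 0))
    stop_validation("survival times must be positive and finite")
  if (!all(event %in% c(0, 1)))
    stop_validation("event indicators must be 0 or 1")
  if (anyDuplicated(subject_id))
    stop_validation("duplicate subject_id in survival table")
  df <- data.frame(subject_id = as.character(subject_id), time = time,
                   event = event, stringsAsFactors = FALSE)
  if (!is.null(group)) df$group <- as.character(group)
  if (!is.null(score)) df$score <- as.numeric(score)
  class(df) <- c("SurvivalTable", "data.frame")
  df
}

#' Write a survival table as CSV
#' @param tab A `SurvivalTable`.
#' @param path Output path.
#' @export
write_survival_csv <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' Validate a directory of pipeline inputs and print a report
#'
#' Looks for the on-disk layout written by [write_cohort()] (matrix.mtx +
#' features.tsv + barcodes.tsv + cell_meta.csv, optional contigs.csv,
#' survival.csv, sets.gmt) and reports which components parse cleanly.
#'
#' @param dir Directory to validate.
#' @return Invisibly, a named list of "ok"/error-message strings.
#' @export
validate_input_dir <- function(dir) {
  check <- function(expr) tryCatch({ force(expr); "ok" }, error = function(e) conditionMessage(e))
  res <- list()
  res$expression <- check(read_mtx_bundle(file.path(dir, "matrix.mtx"),
                                          file.path(dir, "features.tsv"),
                                          file.path(dir, "barcodes.tsv"),
                                          file.path(dir, "cell_meta.csv")))
  if (file.exists(file.path(dir, "contigs.csv")))
    res$contigs <- check(read_contig_csv(file.path(dir, "contigs.csv")))
  if (file.exists(file.path(dir, "survival.csv")))
    res$survival <- check(read_survival_csv(file.path(dir, "survival.csv")))
  if (file.exists(file.path(dir, "sets.gmt")))
    res$gene_sets <- check(read_gmt(file.path(dir, "sets.gmt")))
  for (nm in names(res)) cat(sprintf("%-10s %s\n", nm, res[[nm]]))
  invisible(res)
}
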