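# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores (or removes) the global `.Random.seed` on exit so that seeded
#' package functions never perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv) else if (exists(".Random.seed", envir = genv, inherits = FALSE)) rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed, kept inside 32-bit integer range.
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1000003 + k * 7919) %% 2147483647L)
}

stop_format <- function(...) {
  stop(structure(class = c("tmekit_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_validation <- function(...) {
  stop(structure(class = c("tmekit_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce any matrix-like object to a column-compressed double sparse matrix.
as_dgc <- function(m) {
  if (inherits(m, "dgCMatrix")) return(m)
  if (is.matrix(m)) m <- Matrix::Matrix(m, sparse = TRUE, doDiag = FALSE)
  m <- methods::as(m, "CsparseMatrix")
  if (!methods::is(m, "dMatrix")) m <- methods::as(m, "dMatrix")
  if (!methods::is(m, "generalMatrix")) m <- methods::as(m, "generalMatrix")
  methods::as(m, "CsparseMatrix")
}
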