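# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so package functions never clobber the user's stream.
#' A `NULL` seed evaluates `expr` under the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed; stays well below .Machine$integer.max.
derive_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# assert x is a numeric matrix with unique dimnames
check_matrix <- function(m, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stopf("%s must be a numeric matrix", what)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stopf("%s must have row and column names", what)
  if (anyDuplicated(rownames(m)))
    stopf("duplicate feature ids in %s", what)
  if (anyDuplicated(colnames(m)))
    stopf("duplicate sample ids in %s", what)
  invisible(m)
}

# closed vocabulary of gene functional subregions plus the intergenic bucket
SUBREGIONS <- c("TSS1500", "TSS200", "5UTR", "FirstExon", "Body", "3UTR")
PROMOTER_SUBREGIONS <- c("TSS1500", "TSS200", "5UTR", "FirstExon")
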