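# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's RNG stream. A `NULL` seed evaluates the expression as-is.
#' @param seed integer seed or `NULL`
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

# Frobenius norm
fnorm <- function(M) sqrt(sum(M * M))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

# Ensure a numeric matrix with finite entries; used at module boundaries.
check_matrix <- function(M, what) {
  if (!is.matrix(M) || !is.numeric(M)) {
    stopf("%s must be a numeric matrix", what)
  }
  if (anyNA(M) || !all(is.finite(M))) {
    stopf("%s contains non-finite values", what)
  }
  invisible(M)
}
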