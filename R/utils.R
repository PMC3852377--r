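#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded package functions do not disturb the global
#' random-number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Sample one categorical value per row of a probability matrix (rows need
# not be normalised). Returns integer column indices.
row_categorical <- function(p) {
  k <- ncol(p)
  cs <- p
  for (j in seq_len(k)[-1L]) cs[, j] <- cs[, j - 1L] + p[, j]
  u <- stats::runif(nrow(p)) * cs[, k]
  1L + as.integer(rowSums(cs < u))
}

# m independent categorical draws per row; returns an nrow(p) x m integer
# matrix. Used by the Monte-Carlo IBD sampler where many replicate draws
# from the same per-individual marginals are needed.
row_categorical_many <- function(p, m) {
  n <- nrow(p)
  k <- ncol(p)
  cs <- p
  for (j in seq_len(k)[-1L]) cs[, j] <- cs[, j - 1L] + p[, j]
  cs <- cs / cs[, k]
  u <- matrix(stats::runif(n * m), n, m)
  out <- matrix(1L, n, m)
  for (j in seq_len(k - 1L)) out <- out + (u > cs[, j])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_lcq <- function(...) stop(..., call. = FALSE)
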