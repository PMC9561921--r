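#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' seeded package internals do not disturb user-level randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  eval.parent(substitute(expr))
}

#' Numerically stable softmax over matrix columns
#'
#' @param x Numeric matrix; the softmax is taken down each column.
#' @return Matrix of the same shape with nonnegative columns summing to 1.
#' @keywords internal
softmax_cols <- function(x) {
  x <- sweep(x, 2L, apply(x, 2L, max), "-")
  ex <- exp(x)
  sweep(ex, 2L, colSums(ex), "/")
}

# Derive a stream of distinct 31-bit sub-seeds from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
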