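#' @keywords internal
"_PACKAGE"

# Numeric epsilon used to clamp probabilities before log / inside softmax.
.CYTODX_EPS <- 1e-12

#' Evaluate an expression under a local RNG seed
#'
#' Saves the global RNG state, seeds it with `seed`, evaluates `expr`, and
#' restores the previous state, so generators are pure functions of their seed.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible substream seed
#'
#' Maps a top-level seed plus any number of integer indices to a derived
#' seed (below `.Machine$integer.max`) via an LCG-style mix. Used to give
#' every generated image or component its own RNG substream so datasets stay
#' reproducible under partial regeneration.
#'
#' @param seed top-level integer seed.
#' @param ... integer indices identifying the substream.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed) %% 2147483647
  for (k in idx) {
    x <- (x * 48271 + as.double(k) * 8191 + 1) %% 2147483647
  }
  as.integer(x)
}

# Row-wise softmax with max-shift for numerical stability.
softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
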