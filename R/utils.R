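#' Evaluate an expression under a fixed RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so package functions never leak global RNG
#' state. All stochastic functions in the package take explicit seeds
#' and go through this helper.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a sub-seed from a base seed
#'
#' Deterministic stream splitting for multi-stage simulations; keeps the
#' derived seed within 32-bit integer range.
#'
#' @param seed base seed
#' @param k stream index
#' @return integer seed
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629)
}
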