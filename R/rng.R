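# Seed plumbing: every stochastic stage derives its own 31-bit seed from the
# root seed plus a purpose label, so stages are independently reproducible
# and reordering one stage never perturbs another.

#' Derive a stage seed from a root seed
#' @param seed root integer seed.
#' @param purpose short label naming the consumer ("terrain", "layout", ...).
#' @return integer in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, purpose) {
  h <- 0
  for (ch in utf8ToInt(purpose)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h) %% 2147483647)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state, so simulation internals never
#' disturb user-level random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
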