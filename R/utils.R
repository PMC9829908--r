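#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators never disturb the
#' caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# stable per-purpose child seeds from a master seed
child_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483629L
}
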