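# Deterministic seed derivation.
#
# Replicate i of a run must be reproducible from (masterSeed, i) alone so
# replicates can be generated in any order (or in parallel) with identical
# results. Seeds are derived with a few Lehmer multiplicative steps modulo
# the Mersenne prime 2^31 - 1; all products stay below 2^53 so the
# arithmetic is exact in doubles on every platform.

#' Derive a child seed from a master seed and a stream index
#'
#' @param masterSeed integer master seed.
#' @param stream non-negative integer stream index (e.g. replicate
#'   number, or a stage tag).
#' @return An integer in 1 .. 2^31 - 2, usable with [set.seed()].
#' @examples
#' deriveSeed(42, 1) != deriveSeed(42, 2)
#' @export
deriveSeed <- function(masterSeed, stream) {
  m <- 2147483647
  h <- abs(as.numeric(masterSeed)) %% m
  h <- (h * 48271) %% m
  h <- (h + (abs(as.numeric(stream)) %% m)) %% m
  h <- (h * 48271) %% m
  h <- (h * 69621) %% m
  if (h == 0) h <- 1
  as.integer(h)
}

# run `expr` under a local RNG state seeded with `seed`; restores the
# caller's RNG so library code never perturbs user-level randomness
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
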