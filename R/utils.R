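# Internal helpers.

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG stream untouched.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive k child seeds (< 2^31) from a master seed, independent of the
# caller's RNG state.
.childSeeds <- function(seed, k) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, k))
}

.isCount <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}
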