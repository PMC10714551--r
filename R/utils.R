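# Internal helpers: seed fan-out and small numerics.

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministically derive `n` child seeds (31-bit) from a master seed.
# Used to give every locus/replicate its own substream so per-locus results
# are reproducible independent of execution order.
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# harmonic-number helpers used throughout the neutrality tests
harmonicA1 <- function(n) sum(1 / seq_len(n - 1))
harmonicA2 <- function(n) sum(1 / seq_len(n - 1)^2)

`%||%` <- function(a, b) if (is.null(a)) b else a
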