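# Evaluate an expression under a temporary RNG state, restoring the caller's
# stream afterwards. All stochastic package code funnels through this, so a
# SamplingDesign seed fixes results without clobbering user RNG state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Child seeds for the independent random phases of one design seed, derived
# by multiplicative hashing so that arithmetically related user seeds (e.g.
# consecutive integers used for a replicate and its cell pattern) do not
# yield correlated generator states.
.hashSeed <- function(seed, salt) {
  # one Lehmer step; operands stay below 2^53 so the modulus is exact
  x <- (as.double(seed %% 65536L) + 65536 * salt) * 48271
  as.integer(x %% 2147483647)
}
.fovPhaseSeed  <- function(seed) .hashSeed(seed, 101)
.gridPhaseSeed <- function(seed) .hashSeed(seed, 202)
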