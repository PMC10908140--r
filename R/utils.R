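# Internal utilities: seed derivation and local RNG streams.
#
# A single user-facing seed fans out to per-stage seeds by hashing the stage
# name, so each pipeline stage (split, balancing, weight init, batching, ...)
# is independently reproducible and reordering stages does not silently
# change downstream draws.

# 32-bit string hash (FNV-1a style, kept below 2^31-1 for set.seed)
hash_stage <- function(seed, name) {
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(paste0(name, ":", seed))) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483647)
}

# An isolated RNG stream: an environment carrying its own .Random.seed so
# package randomness never perturbs (nor is perturbed by) the caller's RNG.
rng_stream <- function(seed, name) {
  env <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(hash_stage(seed, name))
  env$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  env
}

with_rng <- function(rng, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  eval.parent(substitute(expr))
}

rng_sample <- function(rng, x, n) with_rng(rng, x[sample.int(length(x), n)])
rng_runif <- function(rng, n, min = 0, max = 1) with_rng(rng, runif(n, min, max))
rng_rnorm <- function(rng, n, mean = 0, sd = 1) with_rng(rng, rnorm(n, mean, sd))
rng_rpois <- function(rng, n, lambda) with_rng(rng, rpois(n, lambda))
rng_rt <- function(rng, n, df) with_rng(rng, rt(n, df))
rng_shuffle <- function(rng, x) with_rng(rng, x[sample.int(length(x))])

`%||%` <- function(a, b) if (is.null(a)) b else a
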