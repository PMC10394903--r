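# internal helpers shared across modules

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library randomness never leaks into
# user code.
withLocalSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed %% .Machine$integer.max))
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# dense numeric matrix from either base matrix or Matrix
asDense <- function(v) {
  if (is(v, "Matrix")) as.matrix(v) else v
}

# Euclidean norm
l2norm <- function(x) sqrt(sum(x^2))

# shared gene universe of two id vectors, preserving the first's order
sharedGenes <- function(a, b) a[a %in% b]

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
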