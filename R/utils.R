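# Internal helpers.

# Evaluate expr with a local RNG state: seeds deterministically, then
# restores whatever global .Random.seed was in place.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# choose(n, 2) vectorised without overflow surprises
.pairs <- function(n) n * (n - 1) / 2

# empirical p-value with the +1 correction
.empP <- function(nExtreme, nNull) (1 + nExtreme) / (1 + nNull)
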