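# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a base seed and an index, kept within 32-bit range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# softmax over columns of a matrix, numerically stabilised
col_softmax <- function(m) {
  m <- sweep(m, 2, apply(m, 2, max), "-")
  e <- exp(m)
  sweep(e, 2, colSums(e), "/")
}
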