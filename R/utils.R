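# internal helpers

# Deterministic child seed for a named stage so that one user-facing seed
# drives every source of randomness without streams colliding.
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.double(seed)) * 48271 + stream * 69621) %% 2147483629)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Column standardization to mean 0, sd 1; constant columns are set to zero
# (they can neither be selected nor select anything in a lasso).
standardize_cols <- function(x) {
  x <- sweep(x, 2L, colMeans(x), "-")
  s <- sqrt(colMeans(x^2))
  s[s == 0] <- Inf
  sweep(x, 2L, s, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
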