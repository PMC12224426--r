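# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.is_square <- function(M) is.matrix(M) && nrow(M) == ncol(M)

# Derive a stream of sub-seeds from one user-visible seed; kept below 2^31.
.derive_seeds <- function(seed, n) {
  (as.numeric(seed) * 1000003 + 7919 * seq_len(n)) %% 2147483647
}
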