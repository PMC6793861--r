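# Run code with a local RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic per-cell seed derived from a root seed; kept inside the
# 32-bit integer range so results are portable.
derive_seed <- function(root, index) {
  as.integer((as.double(root) * 48271 + as.double(index) * 16807) %% 2147483587)
}

frobenius <- function(m) sqrt(sum(m^2))
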