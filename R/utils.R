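# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# The seed is scrambled through one Mersenne-Twister output before the
# final seeding: R initializes the MT state from the seed with an LCG, so
# streams started from consecutive seeds (the per-subject substream
# scheme) are measurably correlated in their first draws; re-seeding from
# a tempered MT output decorrelates them.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  set.seed(sample.int(2147483646L, 1))
  force(code)
}

# Row-wise Euclidean norms.
row_norms <- function(m) sqrt(rowSums(m * m))

# Row-wise cross product of two n x 3 matrices.
row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
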