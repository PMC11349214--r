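# Internal helpers shared across modules.

# Run `expr` under a local RNG state seeded with `seed`, restoring the caller's
# state afterwards so package functions never perturb the session RNG.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# Derive a child seed deterministically; keeps values inside 32-bit range.
# Arithmetic in doubles (exact below 2^53) to avoid integer overflow.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 1009) %% 2147480017)
}

# Stratified fold assignment: preserves the event rate per fold.
stratified_folds <- function(y, n_folds, seed) {
  stopifnot(n_folds >= 2)
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

# All subsets of `x` of size `k` in deterministic combinatorial order,
# as a list of vectors (list(integer(0)) for k = 0).
subsets_of_size <- function(x, k) {
  if (k == 0) return(list(x[0]))
  if (length(x) < k) return(list())
  cmb <- utils::combn(length(x), k)
  lapply(seq_len(ncol(cmb)), function(j) x[cmb[, j]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
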