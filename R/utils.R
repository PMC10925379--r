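# Internal helpers shared across modules.

# Run `code` under a fixed RNG state, restoring the caller's state afterwards.
# All randomness in the package flows through this so that every operation is
# reproducible from an integer seed.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream index, staying well
# inside 32-bit integer range whatever small integer the parent is.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483)
}

# Stratified assignment of n rows (with binary y) into k folds of
# near-equal size; returns an integer vector of fold labels.
stratified_folds <- function(y, k, seed) {
  stopifnot(k >= 2L, length(y) >= k)
  with_seed(seed, {
    fold <- integer(length(y))
    shift <- 0L
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      # rotate the cycle so per-class remainders land on different folds,
      # keeping total fold sizes within 1 of each other
      fold[idx] <- ((seq_along(idx) + shift - 1L) %% k) + 1L
      shift <- shift + length(idx) %% k
    }
    fold
  })
}

# Stratified sample of `size` indices from rows with binary y (without
# replacement), preserving the class mix as closely as integer rounding
# allows.
stratified_sample <- function(y, size, seed) {
  stopifnot(size >= 1L, size <= length(y))
  with_seed(seed, {
    pos <- which(y == 1)
    neg <- which(y == 0)
    n_pos <- round(size * length(pos) / length(y))
    n_pos <- min(max(n_pos, if (size >= 2) 1L else 0L), length(pos), size)
    n_neg <- size - n_pos
    if (n_neg > length(neg)) { n_neg <- length(neg); n_pos <- size - n_neg }
    sort(c(sample(pos, n_pos), sample(neg, n_neg)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) plogis(x)
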