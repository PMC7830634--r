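#' @keywords internal
"_PACKAGE"

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# funnel through this so that no function touches global RNG state.
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
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Deterministically derive a sub-seed from a master seed and a stage index.
# Keeps derived seeds inside 32-bit integer range.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + as.double(index) * 7919) %% 2147483647L)
}

# Stratified fold assignment: each class is split as evenly as possible
# across `k` folds. Returns an integer vector of fold ids (1..k).
stratified_folds <- function(y, k) {
  y <- as.factor(y)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Stratified train/test split; returns list(train=, test=) of row indices.
stratified_split <- function(y, test_frac) {
  y <- as.factor(y)
  test <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_test <- max(1L, round(length(idx) * test_frac))
    test <- c(test, sample(idx, n_test))
  }
  list(train = setdiff(seq_along(y), test), test = sort(test))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
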