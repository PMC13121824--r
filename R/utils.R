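# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
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
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic substream seeds, kept strictly below 2^31 so they remain valid
# R integers. Used to give each layer / replication its own RNG stream.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729 + 11) %%
    2147483629)
}

row_max <- function(x) {
  x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
}

# Row-wise log(sum(exp(x))) with max subtraction.
row_logsumexp <- function(x) {
  mx <- row_max(x)
  finite <- is.finite(mx)
  out <- mx
  if (any(finite)) {
    xs <- x[finite, , drop = FALSE] - mx[finite]
    out[finite] <- mx[finite] + log(rowSums(exp(xs)))
  }
  out
}

# Numerically stable log(1 + exp(x)).
log1pexp <- function(x) {
  out <- x
  small <- x <= 18
  out[small] <- log1p(exp(x[small]))
  big <- x > 18 & x < 33
  out[big] <- x[big] + exp(-x[big])
  out
}

# log with exact zeros mapped to a large negative sentinel instead of -Inf, so
# that 0 * log(0) terms vanish inside matrix products.
safe_log <- function(x, floor = -745) {
  out <- log(x)
  out[out < floor] <- floor
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_binary_matrix <- function(x) {
  is.matrix(x) && all(x %in% c(0, 1))
}

assert_binary_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!all(x %in% c(0, 1))) {
    stop(sprintf("%s must contain only 0/1 entries", what), call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}
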