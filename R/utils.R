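# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Every generator in the package is a pure function of (parameters, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# log density of y ~ N(mu, S), dense Cholesky; used for closed-form GLS fits
dmvnorm_log <- function(y, mu, S) {
  n <- length(y)
  R <- chol(S)
  z <- backsolve(R, y - mu, transpose = TRUE)
  -0.5 * n * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

# derive a stream of sub-seeds from one seed, staying below 2^31
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# BM covariance among tips (shared root-to-MRCA path lengths)
bm_vcv <- function(tree) ape::vcv(tree)

`%||%` <- function(a, b) if (is.null(a)) b else a
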