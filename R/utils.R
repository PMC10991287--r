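# Internal helpers shared across modules.

# Evaluate `code` under `set.seed(seed)` without disturbing the caller's
# RNG stream. With seed = NULL the ambient stream is used as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Closed-form ridge regression with an unpenalized intercept; the fast,
# deterministic base learner behind GA fitness and RFE ranking.
ridge_coef <- function(X, y, lambda = 1e-3) {
  Xi <- cbind(`(Intercept)` = 1, X)
  A <- crossprod(Xi)
  diag(A)[-1L] <- diag(A)[-1L] + lambda
  drop(solve(A, crossprod(Xi, y)))
}

ridge_predict <- function(beta, X) {
  drop(cbind(1, X) %*% beta)
}

# Derive a stage seed from a global seed by a fixed counter scheme,
# kept inside the 32-bit integer range.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 101 + stage * 7919) %% 2147483647)
}
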