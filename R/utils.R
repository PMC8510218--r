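# Internal helpers shared across modules.

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# OLS on an intercept-augmented design via QR.  Errors on rank deficiency,
# naming the collinear columns.  Returns hat diagonals alongside the fit so
# leave-one-out quantities are available without refitting.
ols_fit <- function(X, y) {
  X <- as.matrix(X)
  X1 <- cbind("(Intercept)" = rep(1, length(y)), X)
  qrx <- qr(X1)
  if (qrx$rank < ncol(X1)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    bad <- colnames(X1)[setdiff(seq_len(ncol(X1)), keep)]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(X1 %*% beta)
  res <- y - fitted
  h <- rowSums(qr.Q(qrx)^2)
  list(beta = beta, fitted = fitted, residuals = res, h = h)
}

# Exact leave-one-out predictions for OLS via the hat-matrix identity
# e_(-i) = e_i / (1 - h_i).  With a zero-column X this reduces to the
# intercept-only baseline: each left-out point predicted by the mean of the
# remaining responses.
ols_loo <- function(X, y) {
  f <- ols_fit(X, y)
  if (any(f$h > 1 - 1e-10)) {
    stop("leave-one-out prediction undefined: removing at least one ",
         "observation leaves a rank-deficient refit", call. = FALSE)
  }
  e <- f$residuals / (1 - f$h)
  list(predictions = y - e, errors = e, fit = f)
}

r2_of_fit <- function(y, fitted) {
  1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
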