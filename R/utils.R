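# Internal helpers shared across modules.

# Mix a user seed with stage/fold/learner indices into a valid 32-bit seed.
.deriveSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (k in idx) s <- (s * 48271 + as.numeric(k) + 1) %% 2147483647
  as.integer(s)
}

# Run expr with a local RNG state so callers' streams are untouched.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Row means / variances without matrixStats.
.rowVars <- function(x, means = rowMeans(x)) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  rowSums((x - means)^2) / (n - 1)
}

# Vectorized per-row two-sample pooled t-test (equal-variance form).
# Returns t, df, p, group means, pooled variance. Zero-variance rows get t = 0.
.rowPooledT <- function(x, idx_a, idx_b) {
  xa <- x[, idx_a, drop = FALSE]
  xb <- x[, idx_b, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- .rowVars(xa, ma); vb <- .rowVars(xb, mb)
  df <- na + nb - 2
  s2 <- ((na - 1) * va + (nb - 1) * vb) / df
  se <- sqrt(s2 * (1 / na + 1 / nb))
  t <- ifelse(se > 0, (ma - mb) / se, 0)
  p <- ifelse(se > 0, 2 * stats::pt(-abs(t), df), 1)
  list(t = t, df = df, p = p, mean_a = ma, mean_b = mb, s2 = s2,
       n_a = na, n_b = nb)
}

# Newton solve of trigamma(x) = y, vectorized (used by the variance prior fit).
.trigammaInverse <- function(y) {
  out <- y
  ok <- is.finite(y) & y > 0
  out[!ok] <- NA_real_
  out[is.finite(y) & y > 1e7] <- 1 / sqrt(y[is.finite(y) & y > 1e7])
  x <- 0.5 + 1 / y[ok]
  for (i in seq_len(50)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y[ok]) / psigamma(x, deriv = 2)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  out[ok] <- x
  out
}

.stopIfNot <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}
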