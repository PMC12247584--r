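# Independent brute-force oracles used to cross-check the package's
# vectorized / compiled implementations.

# Nested-loop network summaries over the full matrix (double loop over ROI
# pairs, no vectorization shared with summarize_networks).
oracle_summaries <- function(mat, roles) {
  R <- nrow(mat)
  acc <- list(within = c(), between = c(), extra = c(), hipp = c())
  for (i in 2:R) {
    for (j in 1:(i - 1)) {
      a <- roles[i]; b <- roles[j]; v <- mat[i, j]
      if (a == "DMN-C" && b == "DMN-C") acc$within <- c(acc$within, v)
      if ((a == "DMN-C" && b == "DMN-A") || (a == "DMN-A" && b == "DMN-C")) {
        acc$between <- c(acc$between, v)
      }
      if ((a == "DMN-C" && b == "other") || (b == "DMN-C" && a == "other")) {
        acc$extra <- c(acc$extra, v)
      }
      if (xor(a == "Hipp", b == "Hipp")) acc$hipp <- c(acc$hipp, v)
    }
  }
  lapply(acc, mean)
}

# Residualize-then-Pearson edge selection oracle: partial r of each edge with
# y given covariates equals the Pearson correlation of the lm residuals.
oracle_select_edges <- function(X, y, Z, alpha) {
  if (is.null(Z) || NCOL(Z) == 0) {
    rx <- scale(X, scale = FALSE)
    ry <- y - mean(y)
    cvec <- as.numeric(cor(X, y))
    c_used <- 0
  } else {
    Zf <- cbind(1, as.matrix(Z))
    rx <- qr.resid(qr(Zf), X)
    ry <- qr.resid(qr(Zf), y)
    cvec <- as.numeric(cor(rx, ry))
    c_used <- ncol(as.matrix(Z))
  }
  df <- nrow(X) - 2 - c_used
  tval <- cvec * sqrt(df / (1 - cvec^2))
  p <- 2 * pt(-abs(tval), df)
  list(pos = !is.na(p) & p < alpha & cvec > 0,
       neg = !is.na(p) & p < alpha & cvec < 0,
       r = cvec, p = p)
}

# Scalar Fisher-z averaging oracle.
oracle_fisher_mean <- function(rs) tanh(mean(atanh(rs)))

# Random correlation matrix with block structure; PSD by construction
# (factor model plus diagonal).
random_correlation <- function(R, n_factors = 3, seed = 1) {
  set.seed(seed)
  L <- matrix(rnorm(R * n_factors, 0, 0.4), R, n_factors)
  S <- tcrossprod(L) + diag(runif(R, 0.5, 1))
  d <- sqrt(diag(S))
  S / tcrossprod(d)
}
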