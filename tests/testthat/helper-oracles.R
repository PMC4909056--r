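# Independent oracles used across the suite.

# Brute-force Gaussian (restricted) log-likelihood through an explicit dense
# covariance matrix; O(n^3), usable only on small instances.
dense_lmm_loglik <- function(y, provenance, block, variances,
                             method = "REML", X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  Zp <- stats::model.matrix(~ 0 + factor(provenance))
  Zb <- stats::model.matrix(~ 0 + factor(block))
  V <- variances[1] * tcrossprod(Zp) + variances[2] * tcrossprod(Zb) +
    variances[3] * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  quad <- drop(t(r) %*% Vi %*% r)
  ldV <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  p <- ncol(X)
  if (method == "REML") {
    -0.5 * ((n - p) * log(2 * pi) + ldV +
              as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) + quad)
  } else {
    -0.5 * (n * log(2 * pi) + ldV + quad)
  }
}

# Definitional Pearson correlation via explicit sums of products.
brute_pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Balanced trait table with exactly zero provenance and block contrasts:
# subtracting the factor means of a balanced crossed layout puts the REML
# estimates of both variance components exactly on the zero boundary.
make_boundary_data <- function(seed, n_prov = 6, n_block = 3, n_rep = 4) {
  set.seed(seed)
  prov <- factor(rep(seq_len(n_prov), each = n_block * n_rep))
  block <- factor(rep(rep(seq_len(n_block), each = n_rep), n_prov))
  y <- rnorm(length(prov), 10, 2)
  y <- y - ave(y, prov) - ave(y, block) + 2 * mean(y)
  list(y = y, provenance = prov, block = block)
}
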