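# Independent reference implementations used as oracles by the tests.
# Deliberately naive: loops and textbook formulas, no shared code with the
# package internals.

# Coordinate-descent solver for the weighted LASSO
#   min 0.5 * ||y - X b||^2 + lambda * sum(delta_j * |b_j|)
# (no intercept, no standardization). Warm-startable via beta0.
cd_weighted_lasso <- function(X, y, lambda, delta = rep(1, ncol(X)),
                              beta0 = numeric(ncol(X)),
                              tol = 1e-13, max_iter = 200000L) {
  beta <- beta0
  xx <- colSums(X^2)
  r <- y - X %*% beta
  for (it in seq_len(max_iter)) {
    delta_max <- 0
    for (j in seq_len(ncol(X))) {
      if (xx[j] == 0) next
      bj_old <- beta[j]
      rho <- sum(X[, j] * r) + xx[j] * bj_old
      bj <- sign(rho) * max(abs(rho) - lambda * delta[j], 0) / xx[j]
      if (bj != bj_old) {
        r <- r - X[, j] * (bj - bj_old)
        delta_max <- max(delta_max, abs(bj - bj_old))
        beta[j] <- bj
      }
    }
    if (delta_max < tol) break
  }
  beta
}

# The penalty level of an adaptive-LARS knot: the weighted LASSO KKT
# stationarity gives lambda = max_j |x_j^T r| / delta_j at the knot.
knot_lambda <- function(X, y, beta, delta) {
  r <- y - X %*% beta
  max(abs(crossprod(X, r)) / delta)
}

# Naive double-loop evaluation of the difference-equation right-hand side for
# one (gene, transition, replicate) row: G + A + I of the model.
naive_row_value <- function(ds, b, w, a, d_weights, inputs, gene, m, r) {
  genes <- ds$genes
  tfs <- rownames(b)
  val <- 0
  for (k in tfs)
    if (b[k, gene] == 1)
      for (j in genes)
        if (b[k, j] == 0)
          val <- val + w[k, j] * ds$values[j, m - 1L, r]
  val <- val + a[gene] * ds$values[gene, m - 1L, r]
  for (u in inputs)
    val <- val + d_weights[u$id, gene] * eval_input(u, ds$times[m - 1L])
  as.numeric(val)
}

# Matrix-exponential solution of dx/dt = A x (input-free linear system).
expm_solution <- function(A, x0, times) {
  t(vapply(times, function(t)
    as.numeric(Matrix::expm(A * t) %*% x0), numeric(length(x0))))
}

# Random expression dataset on a given grid.
random_dataset <- function(n_genes, times, R) {
  expression_dataset(
    array(stats::rnorm(n_genes * length(times) * R),
          dim = c(n_genes, length(times), R)),
    genes = paste0("g", seq_len(n_genes)), times = times)
}
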