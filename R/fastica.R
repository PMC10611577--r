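# Internal spatial source separation: PCA whitening followed by symmetric
# FastICA with the logcosh contrast. Operates on a voxels x time matrix and
# returns spatially independent component maps plus their timecourses.
# Deterministic for a fixed seed (random orthogonal initialisation).

symDecorrelate <- function(W) {
  e <- eigen(crossprod(W), symmetric = TRUE)
  W %*% (e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)),
                            length(e$values)) %*% t(e$vectors))
}

# X: V x T matrix of (detrended) voxel timecourses; k components
spatialICA <- function(X, k, seed = 1, maxit = 500, tol = 1e-9) {
  V <- nrow(X)
  Xc <- X - rowMeans(X)
  Xc <- sweep(Xc, 2, colMeans(Xc))
  sv <- svd(Xc, nu = k, nv = 0)
  stopIf(length(sv$d) < k || sv$d[k] < 1e-12 * sv$d[1L],
         "requested more components than the data support")
  Z <- sqrt(V) * sv$u                     # V x k, whitened spatial data
  W <- withSeed(seed, {
    matrix(stats::rnorm(k * k), k, k)
  })
  W <- symDecorrelate(W)
  for (it in seq_len(maxit)) {
    S <- Z %*% W                          # V x k candidate sources
    G <- tanh(S)
    W1 <- crossprod(Z, G) / V - sweep(W, 2, colMeans(1 - G^2), "*")
    W1 <- symDecorrelate(W1)
    conv <- max(abs(abs(colSums(W1 * W)) - 1))
    W <- W1
    if (conv < tol) break
  }
  S <- Z %*% W                            # V x k spatial sources, unit var
  # deterministic sign: positive skewness (loadings point into the network)
  sgn <- ifelse(colSums(S^3) < 0, -1, 1)
  S <- sweep(S, 2, sgn, "*")
  # deterministic order: by explained variance of the back-projection
  A <- crossprod(Xc, S) / V               # T x k mixing timecourses
  ord <- order(colSums(A^2), decreasing = TRUE)
  list(S = S[, ord, drop = FALSE], A = A[, ord, drop = FALSE])
}
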