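# shared fixtures, all generated in code

# two disjoint rectangular network masks on a small grid
smallMaskPair <- function(dims = c(12, 12, 8)) {
  dmn <- array(FALSE, dims); dmn[1:4, 3:8, 2:6] <- TRUE
  cen <- array(FALSE, dims); cen[9:12, 3:8, 2:6] <- TRUE
  list(dims = dims, dmn = dmn, cen = cen)
}

diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# top-fraction voxel set of a loading field (independent of the package's
# thresholding code path: plain order on the flattened field)
topVoxels <- function(field, n) {
  idx <- order(-field, seq_along(field))[seq_len(n)]
  out <- array(FALSE, dim(field)); out[idx] <- TRUE
  out
}

# batch OLS of each tracked voxel's history on [1, t]: the brute-force
# oracle for the incremental engine
batchOLSCoefs <- function(history) {
  # history: t x V matrix
  tt <- seq_len(nrow(history))
  X <- cbind(1, tt)
  B <- qr.coef(qr(X), history)
  list(intercept = B[1L, ], slope = B[2L, ])
}
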