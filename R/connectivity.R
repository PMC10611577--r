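#' Framewise displacement
#'
#' Power-style framewise displacement: the sum of absolute frame-to-frame
#' changes of the three translations (mm) plus the three rotations (radians)
#' converted to arc length on a sphere of the given head radius. The first
#' frame is 0 by convention.
#'
#' @param motion T x 6 matrix: translations (mm) then rotations (radians).
#' @param headRadius sphere radius for the rotation-to-mm conversion
#'   (default 50 mm).
#' @return numeric FD series (mm), length T.
#' @examples
#' m <- matrix(0, 5, 6); m[3, 1:2] <- c(0.3, 0.4)
#' framewiseDisplacement(m)[3]  # 0.7
#' @export
framewiseDisplacement <- function(motion, headRadius = 50) {
  motion <- as.matrix(motion)
  stopIf(ncol(motion) != 6L, "motion must have 6 columns")
  stopIf(nrow(motion) < 2L, "need at least 2 frames")
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
               headRadius * rowSums(d[, 4:6, drop = FALSE]))
  fd
}

#' Flag motion/global-signal outlier volumes
#'
#' ART-style outlier detection: a volume is flagged when its global signal
#' z-value exceeds \code{gsThresh} OR its framewise displacement exceeds
#' \code{fdThresh}. The default thresholds are the lenient preset
#' (z > 5, FD > 0.9 mm); \code{preset = "stringent"} uses z > 3, FD > 0.5 mm.
#'
#' @param series a \linkS4class{VolumeSeries}, used to compute the global
#'   (in-brain mean) signal; may be NULL if \code{gsZ} is supplied.
#' @param fd framewise displacement series.
#' @param gsZ optional precomputed z-scored global signal (overrides
#'   \code{series}).
#' @param gsThresh,fdThresh explicit thresholds (override the preset).
#' @param preset "lenient" (5 / 0.9) or "stringent" (3 / 0.5).
#' @param brainMask logical 3-D array for the global signal; default all
#'   voxels.
#' @return list: \code{outliers} (logical), \code{globalSignalZ},
#'   \code{gsThresh}, \code{fdThresh}.
#' @export
flagOutliers <- function(series = NULL, fd, gsZ = NULL,
                         gsThresh = NULL, fdThresh = NULL,
                         preset = c("lenient", "stringent"),
                         brainMask = NULL) {
  preset <- match.arg(preset)
  if (is.null(gsThresh)) gsThresh <- if (preset == "lenient") 5 else 3
  if (is.null(fdThresh)) fdThresh <- if (preset == "lenient") 0.9 else 0.5
  if (is.null(gsZ)) {
    stopIf(is.null(series), "supply either series or gsZ")
    dat <- volData(series)
    d <- dim(dat)
    Y <- matrix(dat, prod(d[1:3]), d[4L])
    if (!is.null(brainMask)) Y <- Y[maskIndices(brainMask), , drop = FALSE]
    gs <- colMeans(Y)
    s <- stats::sd(gs)
    stopIf(s == 0, "zero-variance global signal")
    gsZ <- (gs - mean(gs)) / s
  }
  stopIf(length(gsZ) != length(fd), "gsZ and fd lengths differ")
  list(outliers = abs(gsZ) > gsThresh | fd > fdThresh,
       globalSignalZ = gsZ, gsThresh = gsThresh, fdThresh = fdThresh)
}

#' Anatomical CompCor noise components
#'
#' Principal components of the detrended timecourses of a noise tissue mask
#' (white matter or CSF): the top right singular vectors of the centered,
#' linearly detrended in-mask data. Columns are unit-norm and mutually
#' orthogonal.
#'
#' @param series a \linkS4class{VolumeSeries}.
#' @param tissueMask logical 3-D array with at least \code{nComponents}
#'   voxels.
#' @param nComponents number of components (default 5 per tissue).
#' @return T x nComponents matrix.
#' @export
compcorComponents <- function(series, tissueMask, nComponents = 5) {
  idx <- maskIndices(tissueMask)
  stopIf(length(idx) < nComponents,
         "tissue mask must contain at least nComponents voxels")
  dat <- volData(series)
  d <- dim(dat)
  Y <- matrix(dat, prod(d[1:3]), d[4L])[idx, , drop = FALSE]  # V x T
  Yd <- detrendColumns(t(Y))                                  # T x V
  Yd <- sweep(Yd, 2, apply(Yd, 2, stats::sd), "/")
  Yd[!is.finite(Yd)] <- 0
  sv <- svd(Yd, nu = nComponents, nv = 0)
  sv$u
}

# ideal FFT band-pass of the columns of a T x V matrix; removes DC
bandpassColumns <- function(Y, tr, band) {
  tlen <- nrow(Y)
  freqs <- seq(0, tlen - 1) / (tlen * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)  # two-sided spectrum
  keep <- freqs >= band[1L] & freqs <= band[2L]
  Yf <- stats::mvfft(Y)
  Yf[!keep, ] <- 0
  Re(stats::mvfft(Yf, inverse = TRUE)) / tlen
}

#' Denoise a run by confound regression and band-pass filtering
#'
#' Builds the standard nuisance design — 12 realignment regressors (6
#' parameters and their first derivatives), 5 + 5 WM/CSF aCompCor
#' components, linear drift and its first derivative, and one spike regressor
#' per flagged outlier frame — then residualizes every voxel against it and
#' band-pass filters. Data and regressors are filtered to the same band
#' before the regression (band-limited residualization), which makes the
#' operation idempotent: running it on its own output returns the input.
#' Collinear design columns (e.g. the derivative of the linear drift, which
#' is constant) are dropped with a warning.
#'
#' @param series a \linkS4class{VolumeSeries}.
#' @param confounds a \linkS4class{ConfoundSet} with T rows.
#' @param band two-sided pass band in Hz (default c(0.008, 0.09)).
#' @param doFilter logical; FALSE residualizes without filtering.
#' @return a denoised \linkS4class{VolumeSeries}.
#' @export
denoiseSeries <- function(series, confounds, band = c(0.008, 0.09),
                          doFilter = TRUE) {
  stopifnot(is(series, "VolumeSeries"), is(confounds, "ConfoundSet"))
  dat <- volData(series)
  d <- dim(dat)
  tlen <- d[4L]
  stopIf(nrow(confounds@motion) != tlen, "confound rows must equal volumes")
  tr <- repetitionTime(series)
  tt <- seq_len(tlen)
  X <- cbind(confounds@motion,
             rbind(0, diff(confounds@motion)),
             confounds@compcorWM, confounds@compcorCSF,
             drift = tt - mean(tt),
             drift_deriv = c(0, diff(tt - mean(tt))))
  if (any(confounds@outliers)) {
    spikes <- sapply(which(confounds@outliers),
                     function(i) as.numeric(tt == i))
    X <- cbind(X, spikes)
  }
  Y <- matrix(dat, prod(d[1:3]), tlen)
  Yt <- t(Y)                                       # T x V
  if (doFilter) {
    Yt <- bandpassColumns(Yt, tr, band)
    X <- bandpassColumns(X, tr, band)
  } else {
    Yt <- scale(Yt, scale = FALSE)
    X <- scale(X, scale = FALSE)
  }
  # drop numerically null / collinear columns
  keep <- apply(X, 2, function(col) sqrt(sum(col^2)) > 1e-10)
  X <- X[, keep, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient confound design: dropping ",
            ncol(X) - qrX$rank, " collinear column(s)")
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  R <- if (ncol(X)) qr.resid(qrX, Yt) else Yt
  VolumeSeries(array(t(R), d), tr = tr, affine = voxelAffine(series))
}

#' Build a spherical seed mask
#'
#' Selects every voxel whose world-space center lies within \code{radius} mm
#' of the seed center under the supplied voxel-to-world affine (voxel indices
#' are 0-based, NIfTI convention).
#'
#' @param spec a \linkS4class{SeedSpec}.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param gridDims integer 3-vector.
#' @return logical 3-D array; errors if the sphere misses the grid.
#' @export
makeSphereSeed <- function(spec, affine, gridDims) {
  stopifnot(is(spec, "SeedSpec"))
  g <- as.integer(gridDims)
  ijk <- as.matrix(expand.grid(i = 0:(g[1L] - 1L), j = 0:(g[2L] - 1L),
                               k = 0:(g[3L] - 1L)))
  world <- t(affine %*% t(cbind(ijk, 1)))[, 1:3, drop = FALSE]
  dist2 <- rowSums(sweep(world, 2, spec@center)^2)
  m <- array(dist2 <= spec@radius^2, dim = g)
  stopIf(!any(m), "sphere does not intersect the grid")
  m
}

#' Seed-based Fisher-z connectivity map
#'
#' Correlates the mean timecourse over the seed voxels with every voxel's
#' timecourse and applies the Fisher z (atanh) transform, capping |r| just
#' inside 1 so the map is finite everywhere. Seed voxels report the
#' correlation of their own series with the seed mean as computed (no
#' masking out). Zero-variance voxels get z = 0 and are flagged as
#' degenerate.
#'
#' @param series a (denoised) \linkS4class{VolumeSeries} with >= 10 volumes.
#' @param seedVoxels logical 3-D array of seed membership.
#' @param seed optional \linkS4class{SeedSpec} recorded in the result.
#' @return A \linkS4class{ConnectivityMap}.
#' @export
seedConnectivity <- function(series, seedVoxels, seed = NULL) {
  stopifnot(is(series, "VolumeSeries"))
  dat <- volData(series)
  d <- dim(dat)
  stopIf(d[4L] < 10L, "need at least 10 usable volumes")
  stopIf(!identical(dim(seedVoxels), d[1:3]), "seed mask shape mismatch")
  Y <- t(matrix(dat, prod(d[1:3]), d[4L]))          # T x V
  seedTc <- rowMeans(Y[, maskIndices(seedVoxels), drop = FALSE])
  stopIf(stats::sd(seedTc) == 0, "seed timecourse has zero variance")
  sdv <- apply(Y, 2, stats::sd)
  degenerate <- sdv == 0
  r <- rep(0, ncol(Y))
  ok <- !degenerate
  r[ok] <- as.numeric(stats::cor(seedTc, Y[, ok, drop = FALSE]))
  z <- fisherZ(r)
  z[degenerate] <- 0
  if (is.null(seed)) seed <- SeedSpec(c(0, 0, 0), 8, "seed")
  new("ConnectivityMap", z = array(z, d[1:3]), seed = seed,
      nUsableVols = d[4L], degenerate = array(degenerate, d[1:3]))
}

# 26-connectivity connected components of a logical 3-D array;
# returns an integer label array (0 = background)
labelClusters26 <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  nbr <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbr <- nbr[rowSums(abs(nbr)) > 0, ]
  cur <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      k0 <- (v - 1L) %/% (d[1L] * d[2L])
      j0 <- ((v - 1L) %% (d[1L] * d[2L])) %/% d[1L]
      i0 <- (v - 1L) %% d[1L]
      cand <- cbind(i0 + nbr[, 1L], j0 + nbr[, 2L], k0 + nbr[, 3L])
      okc <- cand[, 1L] >= 0 & cand[, 1L] < d[1L] &
        cand[, 2L] >= 0 & cand[, 2L] < d[2L] &
        cand[, 3L] >= 0 & cand[, 3L] < d[3L]
      cand <- cand[okc, , drop = FALSE]
      flat <- cand[, 1L] + d[1L] * (cand[, 2L] + d[2L] * cand[, 3L]) + 1L
      hit <- flat[mask[flat] & labels[flat] == 0L]
      if (length(hit)) {
        labels[hit] <- cur
        queue <- c(queue, hit)
      }
    }
  }
  labels
}

# summarise surviving voxels into a cluster table
clusterTable <- function(surviving, statMap, affine) {
  labs <- labelClusters26(surviving)
  n <- max(labs)
  if (n == 0L)
    return(data.frame(cluster = integer(0), size = integer(0),
                      peak_i = integer(0), peak_j = integer(0),
                      peak_k = integer(0), peak_x = numeric(0),
                      peak_y = numeric(0), peak_z = numeric(0),
                      peak_stat = numeric(0)))
  do.call(rbind, lapply(seq_len(n), function(cl) {
    vox <- which(labs == cl)
    peak <- vox[which.max(abs(statMap[vox]))]
    d <- dim(labs)
    k0 <- (peak - 1L) %/% (d[1L] * d[2L])
    j0 <- ((peak - 1L) %% (d[1L] * d[2L])) %/% d[1L]
    i0 <- (peak - 1L) %% d[1L]
    w <- as.numeric(affine %*% c(i0, j0, k0, 1))[1:3]
    data.frame(cluster = cl, size = length(vox),
               peak_i = i0, peak_j = j0, peak_k = k0,
               peak_x = w[1L], peak_y = w[2L], peak_z = w[3L],
               peak_stat = statMap[peak])
  }))
}

#' Pre/post connectivity change with small-volume FDR correction
#'
#' For each voxel inside the search region, fits the per-subject connectivity
#' change (post minus pre Fisher z) on an intercept plus an optional motion
#' covariate, tests the intercept, corrects the two-tailed p-values with
#' Benjamini-Hochberg within the region (small-volume correction), and
#' reports 26-connected clusters of surviving voxels.
#'
#' @param preMaps,postMaps lists of per-subject \linkS4class{ConnectivityMap}
#'   objects (or 3-D z arrays), paired by position; >= 3 subjects.
#' @param regionMask logical 3-D array: the a-priori search region.
#' @param covariate optional per-subject motion summary (e.g. mean FD
#'   change), centered internally.
#' @param q FDR level (default 0.05).
#' @param affine voxel-to-world matrix for peak coordinates.
#' @return list: \code{tMap}, \code{pMap}, \code{qMap} (3-D arrays, NA
#'   outside the region), \code{surviving} (logical array),
#'   \code{clusters} (data.frame), \code{df}.
#' @export
prepostChange <- function(preMaps, postMaps, regionMask, covariate = NULL,
                          q = 0.05, affine = diag(4)) {
  getZ <- function(m) if (is(m, "ConnectivityMap")) zMap(m) else m
  pre <- lapply(preMaps, getZ); post <- lapply(postMaps, getZ)
  n <- length(pre)
  stopIf(n != length(post), "pre and post lists differ in length")
  stopIf(n < 3L, "need at least 3 paired subjects")
  idx <- maskIndices(regionMask)
  stopIf(length(idx) == 0L, "empty region mask")
  Chg <- sapply(seq_len(n),
                function(s) (post[[s]] - pre[[s]])[idx])   # V x n
  Chg <- matrix(Chg, length(idx), n)
  if (is.null(covariate)) {
    X <- matrix(1, n, 1)
  } else {
    stopIf(length(covariate) != n, "covariate length must equal subjects")
    X <- cbind(1, covariate - mean(covariate))
  }
  df <- n - ncol(X)
  qrX <- qr(X)
  B <- qr.coef(qrX, t(Chg))                 # p x V
  Res <- qr.resid(qrX, t(Chg))              # n x V
  sigma2 <- colSums(Res^2) / df
  XtXinv11 <- chol2inv(qr.R(qrX))[1L, 1L]
  se <- sqrt(sigma2 * XtXinv11)
  tv <- B[1L, ] / se
  tv[se == 0] <- 0
  pv <- 2 * stats::pt(-abs(tv), df)
  qv <- stats::p.adjust(pv, method = "BH")
  mk <- function(v) { a <- array(NA_real_, dim(regionMask)); a[idx] <- v; a }
  tMap <- mk(tv)
  surv <- array(FALSE, dim(regionMask))
  surv[idx] <- qv <= q
  list(tMap = tMap, pMap = mk(pv), qMap = mk(qv), surviving = surv,
       clusters = clusterTable(surv, tMap, affine), df = df)
}

#' Voxelwise brain-behavior correlation map
#'
#' Partial Pearson correlation of the per-subject connectivity value at each
#' voxel with a behavioral score, controlling for an optional motion
#' covariate, thresholded at an uncorrected p, with 26-connected clusters of
#' suprathreshold voxels.
#'
#' @param maps list of per-subject \linkS4class{ConnectivityMap} objects (or
#'   3-D arrays); n >= 4.
#' @param scores per-subject behavioral values (non-constant).
#' @param covariate optional per-subject nuisance values.
#' @param pThresh uncorrected voxelwise threshold (default 0.001).
#' @param brainMask logical 3-D array; default all voxels.
#' @param affine voxel-to-world matrix for peak coordinates.
#' @return list: \code{rMap}, \code{pMap}, \code{suprathreshold},
#'   \code{clusters}, \code{df}.
#' @export
brainBehaviorMap <- function(maps, scores, covariate = NULL,
                             pThresh = 0.001, brainMask = NULL,
                             affine = diag(4)) {
  getZ <- function(m) if (is(m, "ConnectivityMap")) zMap(m) else m
  zs <- lapply(maps, getZ)
  n <- length(zs)
  stopIf(n < 4L, "need at least 4 subjects")
  stopIf(length(scores) != n, "scores length must equal subjects")
  stopIf(stats::sd(scores) == 0, "constant scores: correlation undefined")
  if (is.null(brainMask)) brainMask <- array(TRUE, dim(zs[[1L]]))
  idx <- maskIndices(brainMask)
  M <- sapply(zs, function(z) z[idx])                 # V x n
  M <- matrix(M, length(idx), n)
  if (is.null(covariate)) {
    y <- scores - mean(scores)
    Mc <- t(scale(t(M), scale = FALSE))
    df <- n - 2L
  } else {
    X <- cbind(1, covariate)
    qrX <- qr(X)
    y <- qr.resid(qrX, scores)
    Mc <- t(qr.resid(qrX, t(M)))
    df <- n - 3L
  }
  num <- as.numeric(Mc %*% y)
  den <- sqrt(rowSums(Mc^2) * sum(y^2))
  r <- ifelse(den > 0, num / den, 0)
  r <- pmax(pmin(r, 1), -1)
  tv <- r * sqrt(df) / sqrt(pmax(1 - r^2, 1e-12))
  pv <- 2 * stats::pt(-abs(tv), df)
  mk <- function(v) { a <- array(NA_real_, dim(brainMask)); a[idx] <- v; a }
  rMap <- mk(r)
  supra <- array(FALSE, dim(brainMask))
  supra[idx] <- pv < pThresh
  list(rMap = rMap, pMap = mk(pv), suprathreshold = supra,
       clusters = clusterTable(supra, rMap, affine), df = df)
}

#' Mean within-network connectivity
#'
#' Average Fisher-z connectivity between the mean timecourses of a set of
#' regions of interest (all unordered pairs), the usual summary of
#' within-network coupling.
#'
#' @param series a (denoised) \linkS4class{VolumeSeries}.
#' @param roiMasks list of >= 2 logical 3-D arrays (or
#'   \linkS4class{NetworkMask} objects).
#' @return mean pairwise Fisher z.
#' @export
withinNetworkConnectivity <- function(series, roiMasks) {
  stopIf(length(roiMasks) < 2L, "need at least 2 ROIs")
  masks <- lapply(roiMasks, function(m)
    if (is(m, "NetworkMask")) maskArray(m) else m)
  for (i in seq_along(masks)[-1L])
    if (any(masks[[i]] & masks[[1L]]))
      warning("overlapping ROIs")
  dat <- volData(series)
  d <- dim(dat)
  Y <- t(matrix(dat, prod(d[1:3]), d[4L]))
  tcs <- sapply(masks, function(m)
    rowMeans(Y[, maskIndices(m), drop = FALSE]))
  R <- stats::cor(tcs)
  mean(fisherZ(R[upper.tri(R)]))
}
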