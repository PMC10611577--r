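test_that("framewise displacement follows the arc-length formula", {
  m <- matrix(0, 5, 6)
  expect_equal(framewiseDisplacement(m), rep(0, 5))
  m[3, 1:2] <- c(0.3, 0.4)
  fd <- framewiseDisplacement(m)
  expect_equal(fd[3], 0.7)          # |0.3| + |0.4|
  expect_equal(fd[1], 0)            # first frame by convention
  m2 <- matrix(0, 4, 6); m2[2, 5] <- 0.01
  expect_equal(framewiseDisplacement(m2)[2], 0.5)  # 50 mm * 0.01 rad

  # permuting translation axes (and rotation axes) leaves FD unchanged
  set.seed(2)
  mp <- cbind(matrix(stats::rnorm(30), 10), matrix(stats::rnorm(30) / 50, 10))
  expect_equal(framewiseDisplacement(mp),
               framewiseDisplacement(mp[, c(3, 1, 2, 5, 6, 4)]))
  expect_error(framewiseDisplacement(mp[, 1:5]), "6 columns")
})

test_that("outlier flags apply the OR rule over both criteria and presets", {
  # clean synthetic run: nothing flagged
  set.seed(3)
  ser <- VolumeSeries(array(stats::rnorm(8 * 8 * 4 * 50), c(8, 8, 4, 50)),
                      tr = 1.2)
  fl <- flagOutliers(ser, fd = rep(0.1, 50))
  expect_identical(sum(fl$outliers), 0L)

  # planted 2-mm motion spike exceeds both FD presets
  mot <- simulateMotion(50, spikeProb = 0.08, spikeScale = 2, seed = 4)
  fd <- framewiseDisplacement(mot$params)
  lenient <- flagOutliers(ser, fd = fd)
  stringent <- flagOutliers(ser, fd = fd, preset = "stringent")
  expect_true(all(lenient$outliers[mot$spikeFrames]))
  expect_true(all(stringent$outliers[mot$spikeFrames]))

  # a frame at z = 4, FD = 0.3: flagged only under the stringent preset
  gsZ <- rep(0, 50); gsZ[10] <- 4
  fd2 <- rep(0.3, 50)
  expect_false(flagOutliers(fd = fd2, gsZ = gsZ)$outliers[10])
  expect_true(flagOutliers(fd = fd2, gsZ = gsZ,
                           preset = "stringent")$outliers[10])
  expect_identical(flagOutliers(fd = fd2, gsZ = gsZ,
                                gsThresh = 3.9)$outliers[10], TRUE)
})

test_that("aCompCor components are orthonormal and span planted noise", {
  dims <- c(10, 10, 6); tlen <- 200
  wm <- array(FALSE, dims); wm[, 1:2, ] <- TRUE
  set.seed(5)
  lat <- matrix(stats::rnorm(2 * tlen), tlen, 2)
  arr <- array(stats::rnorm(prod(dims) * tlen, sd = 0.05), c(dims, tlen))
  wts <- matrix(stats::rnorm(sum(wm) * 2), sum(wm), 2)
  for (t in seq_len(tlen)) {
    v <- arr[, , , t]; v[wm] <- v[wm] + wts %*% lat[t, ]; arr[, , , t] <- v
  }
  ser <- VolumeSeries(arr, tr = 1.2)
  cc <- compcorComponents(ser, wm, 2)
  expect_lt(max(abs(crossprod(cc) - diag(2))), 1e-10)
  expect_true(all(stats::cancor(cc, lat)$cor > 0.99))
  cc5 <- compcorComponents(ser, wm, 5)
  expect_identical(ncol(cc5), 5L)   # default per-tissue dimensionality
  expect_error(compcorComponents(ser, array(FALSE, dims)), "at least")
})

test_that("denoising removes confounds, keeps the band-limited target", {
  dims <- c(8, 8, 6); tlen <- 900; tr <- 1.2
  mot <- simulateMotion(tlen, seed = 5)
  set.seed(6)
  target <- as.numeric(rtnf:::bandpassColumns(matrix(stats::rnorm(tlen)),
                                              tr, c(0.008, 0.09)))
  target <- target / stats::sd(target)
  arr <- array(stats::rnorm(prod(dims) * tlen, sd = 0.1), c(dims, tlen))
  for (t in seq_len(tlen))
    arr[, , , t] <- arr[, , , t] + target[t] + 2 * mot$params[t, 1] -
      1.5 * mot$params[t, 4] + 0.05 * t
  ser <- VolumeSeries(arr, tr = tr)
  den <- suppressWarnings(denoiseSeries(ser, ConfoundSet(mot$params)))
  expect_gt(stats::cor(volData(den)[4, 4, 3, ], target), 0.95)
})

test_that("denoising zeroes constants, attenuates out-of-band power, and is idempotent", {
  dims <- c(8, 8, 4); tlen <- 300; tr <- 1.2
  cser <- VolumeSeries(array(7, c(dims, 40)), tr = tr)
  cd <- suppressWarnings(denoiseSeries(cser, ConfoundSet(matrix(0, 40, 6))))
  expect_lt(max(abs(volData(cd))), 1e-10)

  # pure 0.2 Hz sinusoid: power at 0.2 Hz attenuated by far more than 90%
  tt <- seq_len(tlen)
  set.seed(7)
  s <- array(rep(sin(2 * pi * 0.2 * tt * tr), each = prod(dims)),
             c(dims, tlen)) +
    array(stats::rnorm(prod(dims) * tlen, sd = 0.01), c(dims, tlen))
  d2 <- suppressWarnings(denoiseSeries(VolumeSeries(s, tr = tr),
                                       ConfoundSet(matrix(0, tlen, 6))))
  pw <- function(x) Mod(stats::fft(x))[round(0.2 * tlen * tr) + 1]^2
  expect_lt(pw(volData(d2)[3, 3, 2, ]) / pw(s[3, 3, 2, ]), 0.1)

  # second pass changes nothing
  mot <- simulateMotion(tlen, spikeProb = 0.02, spikeScale = 2, seed = 8)
  arr <- array(stats::rnorm(prod(dims) * tlen), c(dims, tlen))
  conf <- ConfoundSet(mot$params,
                      outliers = framewiseDisplacement(mot$params) > 0.9)
  den1 <- suppressWarnings(denoiseSeries(VolumeSeries(arr, tr = tr), conf))
  den2 <- suppressWarnings(denoiseSeries(den1, conf))
  rel <- sqrt(sum((volData(den2) - volData(den1))^2)) /
    sqrt(sum(volData(den1)^2))
  expect_lt(rel, 1e-6)
})

test_that("spherical seeds select voxels by world-space distance", {
  aff <- diag(c(2, 2, 2, 1))
  # brute-force oracle: integer lattice points with |2v - c| <= 8
  center <- c(16, 16, 16)
  cnt <- 0L
  for (i in 0:16) for (j in 0:16) for (k in 0:16)
    if (sum((2 * c(i, j, k) - center)^2) <= 64) cnt <- cnt + 1L
  sp <- makeSphereSeed(SeedSpec(center, 8), aff, c(17, 17, 17))
  expect_identical(sum(sp), cnt)
  expect_identical(sum(sp), 257L)

  # sub-voxel radius on a voxel center: exactly one voxel
  one <- makeSphereSeed(SeedSpec(c(8, 8, 8), 0.9), aff, c(9, 9, 9))
  expect_identical(sum(one), 1L)

  # translating the center by one full voxel preserves cardinality
  spT <- makeSphereSeed(SeedSpec(center + c(2, 0, 0), 8), aff, c(19, 17, 17))
  expect_identical(sum(spT), sum(sp))

  expect_error(makeSphereSeed(SeedSpec(c(1000, 0, 0), 8), aff, c(9, 9, 9)),
               "intersect")
})

test_that("seed connectivity maps are Fisher-z, flagged when degenerate, and scale-invariant", {
  dims <- c(10, 10, 6); tlen <- 300
  set.seed(9)
  net <- array(FALSE, dims); net[3:7, 3:7, 2:4] <- TRUE
  shared <- stats::rnorm(tlen)
  arr <- array(stats::rnorm(prod(dims) * tlen), c(dims, tlen))
  for (t in seq_len(tlen)) {
    v <- arr[, , , t]; v[net] <- v[net] + 1.5 * shared[t]; arr[, , , t] <- v
  }
  seedm <- array(FALSE, dims); seedm[4:5, 4:5, 3] <- TRUE
  ser <- VolumeSeries(arr, tr = 1.2)
  cm <- seedConnectivity(ser, seedm)
  expect_true(all(is.finite(zMap(cm))))
  expect_gt(mean(zMap(cm)[net & !seedm]), mean(zMap(cm)[!net]))

  # affine rescaling of the series leaves the map unchanged
  cm2 <- seedConnectivity(VolumeSeries(3 * arr + 10, tr = 1.2), seedm)
  expect_equal(zMap(cm2), zMap(cm), tolerance = 1e-10)

  # a voxel identical to the seed mean: capped z, still finite
  one <- array(FALSE, dims); one[1, 1, 1] <- TRUE
  cm3 <- seedConnectivity(ser, one)
  expect_true(is.finite(zMap(cm3)[1, 1, 1]))
  expect_equal(zMap(cm3)[1, 1, 1], atanh(1 - 1e-7))

  # constant voxels are zeroed and flagged
  arr2 <- arr; arr2[2, 2, 2, ] <- 5
  cm4 <- seedConnectivity(VolumeSeries(arr2, tr = 1.2), seedm)
  expect_identical(zMap(cm4)[2, 2, 2], 0)
  expect_true(cm4@degenerate[2, 2, 2])

  expect_error(seedConnectivity(VolumeSeries(arr[, , , 1:5, drop = FALSE],
                                             tr = 1.2), seedm), "10")
})

test_that("pre/post change detects planted reductions under small-volume FDR", {
  dims <- c(14, 14, 8)
  region <- array(FALSE, dims); region[4:10, 4:10, 3:6] <- TRUE
  effect <- array(FALSE, dims); effect[5:8, 5:8, 4:5] <- TRUE
  n <- 9
  set.seed(10)
  pre <- lapply(seq_len(n), function(s)
    array(stats::rnorm(prod(dims), 0.5, 0.1), dims))
  post <- lapply(seq_len(n), function(s) {
    a <- pre[[s]] + array(stats::rnorm(prod(dims), 0, 0.1), dims)
    a[effect] <- a[effect] - 0.3
    a
  })
  res <- prepostChange(pre, post, region,
                       covariate = stats::rnorm(n, 0.2, 0.05), q = 0.05)
  expect_true(all(res$surviving[effect]))
  expect_gt(nrow(res$clusters), 0L)
  expect_lt(res$clusters$peak_stat[which.max(res$clusters$size)], 0)

  # a single-voxel mask reduces to one paired test with BH at m = 1
  single <- array(FALSE, dims); single[1, 1, 1] <- TRUE
  r1 <- prepostChange(pre, post, single)
  expect_equal(r1$qMap[1, 1, 1], r1$pMap[1, 1, 1])
  d <- sapply(seq_len(n), function(s) (post[[s]] - pre[[s]])[1, 1, 1])
  tt <- stats::t.test(d)
  expect_equal(r1$tMap[1, 1, 1], unname(tt$statistic), tolerance = 1e-10)

  expect_error(prepostChange(pre[1:2], post[1:2], region), "3")
  expect_error(prepostChange(pre, post, array(FALSE, dims)), "empty")
})

test_that("brain-behavior maps localize a score's neural source", {
  dims <- c(12, 12, 6)
  roi <- array(FALSE, dims); roi[8:10, 8:10, 4:5] <- TRUE
  n <- 9
  set.seed(11)
  u <- stats::rnorm(n)               # subject-level connectivity trait
  maps <- lapply(seq_len(n), function(s) {
    a <- array(stats::rnorm(prod(dims), 0, 1), dims)
    a[roi] <- u[s] + stats::rnorm(sum(roi), 0, 0.2)
    a
  })
  scores <- 10 * u + stats::rnorm(n, 0, 0.3)
  bb <- brainBehaviorMap(maps, scores, covariate = stats::rnorm(n),
                         pThresh = 0.001)
  expect_gt(sum(bb$suprathreshold & roi), 0L)
  expect_lt(sum(bb$suprathreshold & !roi) / sum(!roi), 0.01)
  expect_error(brainBehaviorMap(maps[1:3], scores[1:3]), "4")
  expect_error(brainBehaviorMap(maps, rep(1, n)), "constant")
})

test_that("within-network connectivity averages pairwise ROI coupling", {
  dims <- c(10, 10, 4); tlen <- 400
  set.seed(12)
  r1 <- array(FALSE, dims); r1[1:3, 1:3, ] <- TRUE
  r2 <- array(FALSE, dims); r2[7:9, 1:3, ] <- TRUE
  r3 <- array(FALSE, dims); r3[1:3, 7:9, ] <- TRUE
  r4 <- array(FALSE, dims); r4[7:9, 7:9, ] <- TRUE
  arr <- array(stats::rnorm(prod(dims) * tlen), c(dims, tlen))
  wnc <- withinNetworkConnectivity(VolumeSeries(arr, tr = 1.2),
                                   list(r1, r2, r3, r4))
  expect_lt(abs(wnc), 0.05)          # independent noise: mean z near 0

  # two ROIs fed the same series: capped maximal z
  arr2 <- arr
  for (t in seq_len(tlen)) {
    v <- arr2[, , , t]; v[r2] <- mean(v[r1]); arr2[, , , t] <- v
  }
  wncMax <- withinNetworkConnectivity(VolumeSeries(arr2, tr = 1.2),
                                      list(r1, r2))
  expect_equal(wncMax, atanh(1 - 1e-7))

  expect_warning(withinNetworkConnectivity(VolumeSeries(arr, tr = 1.2),
                                           list(r1, r1)), "overlap")
  expect_error(withinNetworkConnectivity(VolumeSeries(arr, tr = 1.2),
                                         list(r1)), "2")
})
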