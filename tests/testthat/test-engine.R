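test_that("engine initialisation applies the 30-s baseline convention", {
  mk <- smallMaskPair()
  eng <- initEngine(mk$dmn, mk$cen, tr = 1.2)
  expect_identical(eng@nBaseline, 25L)          # ceiling(30 / 1.2)
  eng08 <- initEngine(mk$dmn, mk$cen, tr = 0.8)
  expect_identical(eng08@nBaseline, 38L)

  expect_error(initEngine(mk$dmn, mk$cen, nBaselineVols = 1), ">= 2")
  expect_error(initEngine(array(FALSE, mk$dims), mk$cen), "empty")

  # overlapping voxels are warned about and excluded from both summaries
  ov <- mk$dmn; ov[9, 5, 3] <- TRUE             # one voxel also in CEN
  expect_warning(engOv <- initEngine(ov, mk$cen), "overlap")
  flat <- which(ov & mk$cen)
  expect_false(any(engOv@voxIdx[engOv@dmnPos] %in% flat))
  expect_false(any(engOv@voxIdx[engOv@cenPos] %in% flat))
})

test_that("drift-only input yields zero activation after baseline", {
  mk <- smallMaskPair()
  tlen <- 50
  eng <- initEngine(mk$dmn, mk$cen, nBaselineVols = 20)
  zs <- numeric(tlen)
  for (t in seq_len(tlen)) {
    vol <- array(5 + 0.3 * t, mk$dims)
    up <- updateEngine(eng, vol)
    eng <- up$engine
    zs[t] <- up$dmn
  }
  expect_lt(max(abs(zs[21:tlen])), 1e-6)
})

test_that("a fresh step inside one mask is reported at its amplitude", {
  mk <- smallMaskPair()
  nBase <- 25
  set.seed(5)
  eng <- initEngine(mk$dmn, mk$cen, nBaselineVols = nBase)
  for (t in seq_len(nBase)) {
    up <- updateEngine(eng, array(stats::rnorm(prod(mk$dims)), mk$dims))
    eng <- up$engine
  }
  sdHat <- mean(eng@baselineSD)
  vol <- array(stats::rnorm(prod(mk$dims)), mk$dims)
  vol[mk$cen] <- vol[mk$cen] + 2 * sdHat
  up <- updateEngine(eng, vol)
  expect_equal(up$cen, 2, tolerance = 0.15)     # noise of a 144-voxel mean
  expect_equal(up$dmn, 0, tolerance = 0.15)
  expect_equal(computePDA(up$cen, up$dmn), up$cen - up$dmn)
  expect_false(up$isBaseline)

  expect_error(updateEngine(eng, array(0, c(2, 2, 2))), "shape")
})

test_that("incremental coefficients equal batch OLS at every TR", {
  dmn <- array(FALSE, c(8, 8, 6)); dmn[1:3, , 1:3] <- TRUE
  cen <- array(FALSE, c(8, 8, 6)); cen[6:8, , 4:6] <- TRUE
  set.seed(6)
  tlen <- 40
  arr <- array(stats::rnorm(prod(c(8, 8, 6)) * tlen), c(8, 8, 6, tlen))
  eng <- initEngine(dmn, cen, nBaselineVols = 10)
  vox <- eng@voxIdx
  history <- NULL
  maxDev <- 0
  for (t in seq_len(tlen)) {
    up <- updateEngine(eng, arr[, , , t]); eng <- up$engine
    history <- rbind(history, as.numeric(arr[, , , t])[vox])
    if (t >= 2) {
      oracle <- batchOLSCoefs(history)
      cf <- rtnf:::engineCoefs(eng)
      maxDev <- max(maxDev,
                    max(abs(oracle$intercept - cf$intercept)),
                    max(abs(oracle$slope - cf$slope)))
    }
  }
  expect_lt(maxDev, 1e-8)
})

test_that("PDA follows its sign convention", {
  expect_identical(computePDA(1.0, 1.0), 0)
  expect_identical(computePDA(2.0, 0.5), 1.5)
  expect_identical(computePDA(0.5, 2.0), -1.5)  # DMN > CEN: dot moves down
  expect_error(computePDA(NaN, 0), "finite")
})

test_that("staircase shrinks by 10% after 5 qualifying TRs and caps at 5", {
  st <- initFeedbackState()
  # drive the dot into the upper circle and hold it there
  st <- stepDisplay(st, 10, trIndex = 1)        # dot far above the circle
  for (k in 2:5) st <- stepDisplay(st, 0, trIndex = k)
  expect_equal(unname(st@circleRadiusPx[["upper"]]), 56 * 0.9)
  expect_identical(unname(st@dotY), 0)          # repositioned to center
  expect_identical(unname(st@accum[["upper"]]), 0)
  expect_identical(nrow(st@events), 1L)

  # five full shrink cycles reach the closed-form radius, then freeze
  st <- initFeedbackState()
  for (cycle in 1:7) {
    st <- stepDisplay(st, 10, trIndex = 10 * cycle)
    for (k in 1:4) st <- stepDisplay(st, 0.01, trIndex = 10 * cycle + k)
  }
  expect_equal(unname(st@circleRadiusPx[["upper"]]), 56 * 0.9^5)
  expect_identical(unname(st@shrinkCount[["upper"]]), 5)
  expect_identical(nrow(st@events), 5L)         # 6th and 7th cycles: no-ops

  # per-circle independence: the lower circle still has its full budget
  st <- stepDisplay(st, -(st@dotY + 1) / 0.1, trIndex = 100)
  for (k in 1:4) st <- stepDisplay(st, -0.01, trIndex = 100 + k)
  expect_equal(unname(st@circleRadiusPx[["lower"]]), 56 * 0.9)
})

test_that("qualifying TRs accumulate non-consecutively since the last shrink", {
  st <- initFeedbackState()
  for (k in 1:4) {
    st <- stepDisplay(st, 10, trIndex = 2 * k - 1)   # inside upper circle
    st <- stepDisplay(st, -10.2, trIndex = 2 * k)    # near lower edge, out
    st <- stepDisplay(st, 0.4, trIndex = 100 + k)    # back toward center
  }
  expect_identical(nrow(st@events), 0L)  # trigger never reached
  expect_identical(unname(st@accum[["upper"]]), 4)
})

test_that("a full run respects timing, conservation and gain invariance", {
  mk <- smallMaskPair()
  fb <- simulateFeedbackSeries(mk$dmn, mk$cen, nVols = 125,
                               nBaselineVols = 25, amplitude = 1.5,
                               engagementProb = 0.65, seed = 12)
  eng <- initEngine(mk$dmn, mk$cen, tr = 1.2, nBaselineVols = 25)
  res <- runFeedbackRun(eng, fb$series)
  expect_identical(res@nFeedbackTRs, 100L)      # 150 s minus 30 s baseline
  fbIdx <- !res@baseline
  expect_equal(res@pda[fbIdx], res@cen[fbIdx] - res@dmn[fbIdx])
  expect_equal(timeInTarget(res), mean(res@pda[fbIdx] > 0))

  # radii never increase within a run
  expect_true(all(res@finalState@circleRadiusPx <= 56 + 1e-12))

  # time in target depends only on the PDA sign, not the display gain
  eng2 <- initEngine(mk$dmn, mk$cen, tr = 1.2, nBaselineVols = 25)
  res2 <- runFeedbackRun(eng2, fb$series,
                         state = initFeedbackState(gain = 0.5))
  expect_identical(timeInTarget(res2), timeInTarget(res))

  short <- VolumeSeries(array(0, c(mk$dims, 10)), tr = 1.2)
  engS <- initEngine(mk$dmn, mk$cen, nBaselineVols = 20)
  expect_error(runFeedbackRun(engS, short), "longer")
})

test_that("display lag delays the dot without changing the PDA trace", {
  mk <- smallMaskPair()
  fb <- simulateFeedbackSeries(mk$dmn, mk$cen, nVols = 60,
                               nBaselineVols = 10, seed = 4)
  e1 <- initEngine(mk$dmn, mk$cen, nBaselineVols = 10)
  e2 <- initEngine(mk$dmn, mk$cen, nBaselineVols = 10)
  r0 <- runFeedbackRun(e1, fb$series, lagTRs = 0L)
  r2 <- runFeedbackRun(e2, fb$series, lagTRs = 2L)
  expect_equal(r0@pda, r2@pda)
  fbIdx <- which(!r0@baseline)
  # lagged dot reproduces the unlagged trajectory two TRs later
  expect_equal(r2@dotY[fbIdx[3:20]], r0@dotY[fbIdx[1:18]])
})

test_that("group time-in-target test matches its chance-level null", {
  flat <- groupTargetTest(rep(0.5, 9))
  expect_equal(unname(flat$statistic), 0)
  expect_equal(flat$p.value, 0.5)
  good <- groupTargetTest(c(0.56, 0.58, 0.55, 0.60, 0.57, 0.59, 0.56,
                            0.58, 0.57))
  expect_lt(good$p.value, 0.05)
  expect_error(groupTargetTest(0.6), "2")
})
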