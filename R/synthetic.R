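#' Generate spatially disjoint network loading maps
#'
#' Builds smooth, non-negative spatial loading fields for a set of synthetic
#' brain networks. Each network is a sum of Gaussian blobs confined to its own
#' slab of the grid, so the supra-threshold supports of different networks are
#' disjoint by construction (the grid is partitioned along the first axis).
#'
#' @param gridDims integer 3-vector of grid dimensions, each >= 8.
#' @param nNetworks number of networks (>= 2).
#' @param blobsPerNetwork Gaussian blobs per network.
#' @param seed integer seed; the result is reproducible bit-for-bit.
#' @param blobSigma blob width (voxels).
#' @return A list of \code{nNetworks} 3-D non-negative arrays.
#' @examples
#' maps <- makeNetworkMaps(c(20, 20, 10), 2, 3, seed = 7)
#' sum(maps[[1]] > 0 & maps[[2]] > 0)  # 0: disjoint supports
#' @export
makeNetworkMaps <- function(gridDims, nNetworks = 2, blobsPerNetwork = 3,
                            seed = 1, blobSigma = 2) {
  gridDims <- as.integer(gridDims)
  stopIf(length(gridDims) != 3L || any(gridDims < 8L),
         "gridDims must be a 3-vector with every dimension >= 8")
  stopIf(nNetworks < 2, "nNetworks must be >= 2")
  withSeed(seed, {
    # partition the first axis into one slab per network, with a 1-voxel gap
    bounds <- round(seq(0, gridDims[1L], length.out = nNetworks + 1L))
    ix <- seq_len(gridDims[1L]); iy <- seq_len(gridDims[2L])
    iz <- seq_len(gridDims[3L])
    coords <- expand.grid(x = ix, y = iy, z = iz)
    lapply(seq_len(nNetworks), function(k) {
      lo <- bounds[k] + 1L; hi <- bounds[k + 1L]
      field <- numeric(nrow(coords))
      for (b in seq_len(blobsPerNetwork)) {
        # keep blob centers away from the slab edges
        cx <- stats::runif(1, lo + blobSigma, hi - blobSigma)
        cy <- stats::runif(1, 1 + blobSigma, gridDims[2L] - blobSigma)
        cz <- stats::runif(1, 1 + blobSigma / 2, gridDims[3L] - blobSigma / 2)
        field <- field + exp(-((coords$x - cx)^2 + (coords$y - cy)^2 +
                                 (coords$z - cz)^2) / (2 * blobSigma^2))
      }
      arr <- array(field, dim = gridDims)
      arr[ix < lo | ix > hi, , ] <- 0  # hard support disjointness
      arr[arr < 1e-6] <- 0
      arr / max(arr)
    })
  })
}

#' Generate network timecourses
#'
#' Draws one timecourse per network with a target pairwise correlation between
#' networks (e.g. a negative value to emulate DMN/CEN anticorrelation), or a
#' box-car design.
#'
#' @param nVols number of volumes.
#' @param nNetworks number of networks.
#' @param betweenR target correlation between network timecourses.
#' @param type "gaussian" for unit-variance white Gaussian series,
#'   "lowfreq" for unit-variance band-limited Gaussian series (spontaneous
#'   BOLD fluctuations concentrate below ~0.1 Hz), "boxcar" for alternating
#'   on/off blocks (20-volume period), phase-shifted per network.
#' @param seed integer seed.
#' @param tr repetition time (s), used by the "lowfreq" type.
#' @param band pass band in Hz for the "lowfreq" type.
#' @return T x nNetworks matrix.
#' @export
networkTimecourses <- function(nVols, nNetworks = 2, betweenR = 0,
                               type = c("gaussian", "lowfreq", "boxcar"),
                               seed = 1, tr = 1.2, band = c(0.008, 0.09)) {
  type <- match.arg(type)
  stopIf(abs(betweenR) >= 1, "betweenR must be in (-1, 1)")
  withSeed(seed, {
    if (type == "boxcar") {
      tt <- seq_len(nVols)
      tc <- sapply(seq_len(nNetworks), function(k) {
        as.numeric(((tt - 1 + (k - 1) * 10) %/% 10) %% 2 == 1)
      })
    } else {
      tc <- matrix(stats::rnorm(nVols * nNetworks), nVols)
      if (type == "lowfreq") {
        tc <- bandpassColumns(tc, tr, band)
        tc <- scale(tc)
        attr(tc, "scaled:center") <- attr(tc, "scaled:scale") <- NULL
      }
      Sigma <- matrix(betweenR, nNetworks, nNetworks)
      diag(Sigma) <- 1
      tc <- tc %*% chol(Sigma)
    }
    tc
  })
}

#' Simulate a volumetric BOLD run with planted network structure
#'
#' Voxel signal is the sum of network loading fields times their timecourses,
#' plus a linear scanner drift and Gaussian noise (optionally AR(1)
#' autocorrelated to mimic BOLD noise). The generating quantities are returned
#' alongside as ground truth.
#'
#' @param maps list of 3-D loading fields (as from \code{makeNetworkMaps}).
#' @param timecourses T x K matrix, one column per map (K = length(maps)).
#' @param driftSlope linear drift, signal units per volume.
#' @param noiseSd noise standard deviation (>= 0).
#' @param tr repetition time in seconds.
#' @param seed integer seed.
#' @param ar1 AR(1) coefficient of the noise (0 = white; default 0.3).
#' @return list with elements \code{series} (\linkS4class{VolumeSeries}) and
#'   \code{truth} (list: maps, timecourses, driftSlope, noiseSd, ar1, seed).
#' @examples
#' maps <- makeNetworkMaps(c(10, 10, 8), 2, 2, seed = 1)
#' tc <- networkTimecourses(50, 2, betweenR = -0.3, seed = 1)
#' run <- simulateRun(maps, tc, driftSlope = 0.01, noiseSd = 1, seed = 2)
#' @export
simulateRun <- function(maps, timecourses, driftSlope = 0, noiseSd = 1,
                        tr = 1.2, seed = 1, ar1 = 0.3) {
  stopIf(noiseSd < 0, "noiseSd must be >= 0")
  stopIf(!is.list(maps) || !length(maps), "maps must be a non-empty list")
  timecourses <- as.matrix(timecourses)
  nVols <- nrow(timecourses)
  stopIf(nVols < 10, "need at least 10 volumes")
  stopIf(ncol(timecourses) != length(maps),
         "timecourses must have one column per map")
  dims <- dim(maps[[1L]])
  M <- sapply(maps, as.vector)                    # V x K
  withSeed(seed, {
    sig <- M %*% t(timecourses)                   # V x T
    sig <- sig + rep(driftSlope * seq_len(nVols) - driftSlope,
                     each = nrow(sig))
    if (noiseSd > 0) {
      eps <- matrix(stats::rnorm(length(sig)), nrow(sig))
      if (ar1 != 0) {
        for (t in 2:nVols) eps[, t] <- ar1 * eps[, t - 1L] +
            sqrt(1 - ar1^2) * eps[, t]
      }
      sig <- sig + noiseSd * eps
    }
    series <- VolumeSeries(array(sig, dim = c(dims, nVols)), tr = tr)
    list(series = series,
         truth = list(maps = maps, timecourses = timecourses,
                      driftSlope = driftSlope, noiseSd = noiseSd,
                      ar1 = ar1, seed = seed))
  })
}

#' Scale network maps to a target within-network correlation
#'
#' Replaces each loading field by a binary support (loading above half its
#' maximum) at a uniform amplitude chosen so that two in-network voxels with a
#' shared unit-variance timecourse and independent noise of SD \code{noiseSd}
#' correlate at \code{withinR}: amplitude = noiseSd * sqrt(r / (1 - r)).
#'
#' @param maps list of 3-D loading fields.
#' @param withinR target within-network pairwise correlation (0 < r < 1).
#' @param noiseSd the noise SD that will be used in \code{simulateRun}.
#' @return list of rescaled maps.
#' @export
scaleMapsForCorrelation <- function(maps, withinR, noiseSd) {
  stopIf(withinR <= 0 || withinR >= 1, "withinR must be in (0, 1)")
  stopIf(noiseSd <= 0, "noiseSd must be positive")
  amp <- noiseSd * sqrt(withinR / (1 - withinR))
  lapply(maps, function(m) {
    out <- array(0, dim(m))
    out[m > max(m) / 2] <- amp
    out
  })
}

#' Simulate realignment parameter traces
#'
#' A smooth random-walk baseline on all six rigid-body parameters plus sparse
#' large spikes (sudden head movements). Rotations are stored in radians;
#' conversion to arc millimetres happens only inside
#' \code{\link{framewiseDisplacement}}.
#'
#' @param nVols number of volumes.
#' @param spikeProb per-frame spike probability in [0, 1].
#' @param spikeScale spike amplitude: mm for translations; the rotational
#'   spike is \code{spikeScale / 50} radians (same arc length on a 50-mm
#'   sphere).
#' @param seed integer seed.
#' @param walkSd random-walk step SD (mm; radians are scaled by 1/50).
#' @return list: \code{params} (T x 6 matrix, columns trans_x, trans_y,
#'   trans_z, rot_x, rot_y, rot_z) and \code{spikeFrames} (integer indices of
#'   planted spikes).
#' @export
simulateMotion <- function(nVols, spikeProb = 0, spikeScale = 2, seed = 1,
                           walkSd = 0.01) {
  stopIf(spikeProb < 0 || spikeProb > 1, "spikeProb must be in [0, 1]")
  stopIf(spikeScale < 0, "spikeScale must be non-negative")
  withSeed(seed, {
    steps <- cbind(matrix(stats::rnorm(nVols * 3, sd = walkSd), nVols),
                   matrix(stats::rnorm(nVols * 3, sd = walkSd / 50), nVols))
    steps[1L, ] <- 0
    spikes <- which(stats::runif(nVols) < spikeProb)
    spikes <- spikes[spikes > 1L]
    for (s in spikes) {
      sgn <- sample(c(-1, 1), 6, replace = TRUE)
      steps[s, ] <- steps[s, ] + sgn * c(rep(spikeScale / 3, 3),
                                         rep(spikeScale / (3 * 50), 3))
    }
    params <- apply(steps, 2, cumsum)
    colnames(params) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")
    list(params = params, spikeFrames = spikes)
  })
}

#' Simulate a behavioral mediation cohort
#'
#' Generates the three-variable chain used in the mediation analysis:
#' X (neurofeedback performance) standard normal,
#' M = a*X + noise (connectivity change), Y = b*M + c'*X + noise (state
#' mindfulness change). With the default noise SDs, M and Y have unit
#' variance, so a, b and c' are standardized path coefficients. Defaults
#' follow the standardized paths of the mediation model this package targets
#' (a = -0.67, b = -0.76, c' = 0.18, n = 9).
#'
#' @param nSubjects number of subjects (>= 4).
#' @param a,b,cPrime true standardized path coefficients.
#' @param noiseSdM,noiseSdY noise SDs; defaults make Var(M) = Var(Y) = 1.
#' @param seed integer seed.
#' @return A \linkS4class{BehaviorCohort}.
#' @examples
#' coh <- simulateBehaviorCohort(5000, a = -0.7, b = -0.8, cPrime = 0, seed = 1)
#' @export
simulateBehaviorCohort <- function(nSubjects = 9, a = -0.67, b = -0.76,
                                   cPrime = 0.18,
                                   noiseSdM = NULL, noiseSdY = NULL,
                                   seed = 1) {
  stopIf(nSubjects < 4, "nSubjects must be >= 4")
  if (is.null(noiseSdM)) noiseSdM <- sqrt(max(0, 1 - a^2))
  if (is.null(noiseSdY))
    noiseSdY <- sqrt(max(0, 1 - b^2 - cPrime^2 - 2 * a * b * cPrime))
  stopIf(noiseSdM < 0 || noiseSdY < 0, "noise SDs must be non-negative")
  withSeed(seed, {
    x <- stats::rnorm(nSubjects)
    m <- a * x + noiseSdM * stats::rnorm(nSubjects)
    y <- b * m + cPrime * x + noiseSdY * stats::rnorm(nSubjects)
    new("BehaviorCohort",
        data = data.frame(nf_performance = x, conn_change = m,
                          sms_change = y),
        truePaths = c(a = a, b = b, c_prime = cPrime),
        seed = as.integer(seed))
  })
}

#' Simulate a neurofeedback run series
#'
#' Builds the volumetric series a feedback run streams through the engine: a
#' flat baseline block followed by a feedback block in which the subject is
#' "engaged" on a random subset of TRs. During engaged TRs the CEN voxels
#' are raised by half the differential amplitude and the DMN voxels lowered
#' by the other half (mindful states suppress DMN below, and raise CEN
#' above, their baselines); disengaged TRs carry no differential. Gaussian
#' noise and linear drift are added everywhere. \code{amplitude = 0} gives
#' an exchangeable null run in which DMN and CEN are statistically
#' identical.
#'
#' Engagement is modelled as episodic rather than a sustained constant
#' offset because the engine's evolving nuisance fit absorbs any signal
#' component that looks like baseline-plus-drift; only moment-to-moment
#' state changes are (and should be) fed back.
#'
#' @param dmnMask,cenMask \linkS4class{NetworkMask} objects or logical 3-D
#'   arrays.
#' @param nVols run length in volumes.
#' @param nBaselineVols leading baseline volumes with no engagement.
#' @param amplitude differential activation during engaged TRs, in noise-SD
#'   units (CEN + amplitude/2, DMN - amplitude/2); interpreted in raw signal
#'   units when \code{noiseSd = 0}.
#' @param engagementProb per-TR probability (random pattern) or duty cycle
#'   (blocked pattern) of being engaged during the feedback block.
#' @param pattern "random" draws engagement as independent Bernoulli TRs;
#'   "blocked" lays engaged TRs out on a fixed repeating 5-TR schedule with
#'   the requested duty cycle (episodes of sustained noting separated by
#'   lapses, the same schedule every run).
#' @param noiseSd voxel noise SD.
#' @param driftSlope linear drift, signal units per volume.
#' @param tr repetition time, seconds.
#' @param seed integer seed.
#' @return list: \code{series} (\linkS4class{VolumeSeries}),
#'   \code{engaged} (logical per-TR truth).
#' @export
simulateFeedbackSeries <- function(dmnMask, cenMask, nVols = 125,
                                   nBaselineVols = 25, amplitude = 1.5,
                                   engagementProb = 0.65, noiseSd = 1,
                                   driftSlope = 0.02, tr = 1.2, seed = 1,
                                   pattern = c("random", "blocked")) {
  pattern <- match.arg(pattern)
  dmn <- if (is(dmnMask, "NetworkMask")) maskArray(dmnMask) else
    array(as.logical(dmnMask), dim(dmnMask))
  cen <- if (is(cenMask, "NetworkMask")) maskArray(cenMask) else
    array(as.logical(cenMask), dim(cenMask))
  stopIf(!identical(dim(dmn), dim(cen)), "mask shapes differ")
  stopIf(nVols <= nBaselineVols, "nVols must exceed nBaselineVols")
  withSeed(seed, {
    nFb <- nVols - nBaselineVols
    engaged <- if (pattern == "random") {
      c(rep(FALSE, nBaselineVols), stats::runif(nFb) < engagementProb)
    } else {
      # fixed 5-TR schedule: first round(5 * duty) TRs of each cycle engaged
      cyc <- rep(seq_len(5) <= round(5 * engagementProb), length.out = nFb)
      c(rep(FALSE, nBaselineVols), cyc)
    }
    dims <- dim(dmn)
    arr <- array(stats::rnorm(prod(dims) * nVols, sd = noiseSd),
                 c(dims, nVols))
    drift <- driftSlope * (seq_len(nVols) - 1)
    for (t in seq_len(nVols)) {
      arr[, , , t] <- arr[, , , t] + drift[t]
      if (engaged[t]) {
        scale <- if (noiseSd > 0) noiseSd else 1
        v <- arr[, , , t]
        v[cen] <- v[cen] + amplitude / 2 * scale
        v[dmn] <- v[dmn] - amplitude / 2 * scale
        arr[, , , t] <- v
      }
    }
    list(series = VolumeSeries(arr, tr = tr), engaged = engaged)
  })
}
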