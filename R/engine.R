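#' Initialise the incremental-GLM feedback engine
#'
#' Sets up per-voxel running accumulators for the ordinary least squares of
#' signal on an intercept and a linear drift term, restricted to the union of
#' the two network masks. The first \code{nBaselineVols} volumes form the
#' baseline block (default: a 30-s crosshair period, i.e.
#' \code{ceiling(30 / tr)} volumes — 25 at TR 1.2 s); when it ends, the
#' per-voxel baseline residual SD is frozen and defines the activation scale.
#'
#' Overlapping mask voxels are assigned to neither network summary (a warning
#' is raised), so the two activation estimates never share voxels.
#'
#' @param dmnMask,cenMask \linkS4class{NetworkMask} objects (or logical 3-D
#'   arrays) for the down- and up-regulation targets.
#' @param tr repetition time, seconds.
#' @param nBaselineVols baseline length in volumes (>= 2); default
#'   \code{ceiling(baselineSec / tr)}.
#' @param baselineSec baseline duration used for the default (seconds).
#' @return A \linkS4class{FeedbackEngine}.
#' @export
initEngine <- function(dmnMask, cenMask, tr = 1.2, nBaselineVols = NULL,
                       baselineSec = 30) {
  dmn <- if (is(dmnMask, "NetworkMask")) maskArray(dmnMask) else
    array(as.logical(dmnMask), dim(dmnMask))
  cen <- if (is(cenMask, "NetworkMask")) maskArray(cenMask) else
    array(as.logical(cenMask), dim(cenMask))
  stopIf(!identical(dim(dmn), dim(cen)), "mask shapes differ")
  stopIf(sum(dmn) == 0L || sum(cen) == 0L, "empty network mask")
  if (is.null(nBaselineVols)) nBaselineVols <- ceiling(baselineSec / tr)
  nBaselineVols <- as.integer(nBaselineVols)
  stopIf(nBaselineVols < 2L,
         "nBaselineVols must be >= 2 (baseline variance undefined)")
  overlap <- dmn & cen
  if (any(overlap))
    warning(sum(overlap),
            " overlapping mask voxels assigned to neither network")
  vox <- sort(unique(c(which(dmn), which(cen))))
  nv <- length(vox)
  new("FeedbackEngine",
      dims = dim(dmn), voxIdx = as.integer(vox),
      dmnPos = which(vox %in% which(dmn & !overlap)),
      cenPos = which(vox %in% which(cen & !overlap)),
      n = 0L, st = 0, stt = 0,
      sy = numeric(nv), sty = numeric(nv), syy = numeric(nv),
      nBaseline = nBaselineVols, tr = as.numeric(tr),
      baselineSD = numeric(0))
}

# solve slope/intercept from accumulators (vectorized over voxels)
engineCoefs <- function(engine) {
  n <- engine@n
  den <- n * engine@stt - engine@st^2
  if (n < 2L || den <= 0) {
    slope <- rep(0, length(engine@voxIdx))
    intercept <- if (n > 0) engine@sy / n else rep(0, length(engine@voxIdx))
  } else {
    slope <- (n * engine@sty - engine@st * engine@sy) / den
    intercept <- (engine@sy - slope * engine@st) / n
  }
  list(intercept = intercept, slope = slope)
}

#' Feed one volume to the engine
#'
#' Scores the incoming volume against the nuisance model fitted to all
#' previous volumes, then folds it into the incremental accumulators. Per
#' voxel, the activation is the prediction residual (signal minus the
#' intercept-plus-drift fit extrapolated to the current TR) divided by the
#' frozen baseline residual SD; the network estimate is the mean of these
#' scaled activations over the mask voxels (uniform weights, since masks are
#' binary). Scoring against the previous fit means a fresh activation is
#' reported at its full amplitude before the nuisance model starts absorbing
#' it. Voxels whose baseline residual SD is numerically zero contribute 0.
#' During the baseline block the returned estimates are flagged as baseline.
#'
#' @param engine a \linkS4class{FeedbackEngine}.
#' @param volume 3-D array matching the engine's grid.
#' @return list: \code{engine} (updated), \code{dmn}, \code{cen}
#'   (baseline-SD units), \code{isBaseline}.
#' @export
updateEngine <- function(engine, volume) {
  stopifnot(is(engine, "FeedbackEngine"))
  stopIf(!identical(dim(volume), engine@dims),
         "volume shape does not match engine masks")
  y <- as.numeric(volume[engine@voxIdx])
  t <- engine@n + 1L
  # score the new volume against the fit over volumes 1..t-1
  cfPrev <- engineCoefs(engine)
  resid <- y - (cfPrev$intercept + cfPrev$slope * t)
  # fold the volume into the accumulators
  engine@n <- t
  engine@st <- engine@st + t
  engine@stt <- engine@stt + as.numeric(t)^2
  engine@sy <- engine@sy + y
  engine@sty <- engine@sty + t * y
  engine@syy <- engine@syy + y^2
  if (t == engine@nBaseline && length(engine@baselineSD) == 0L) {
    # freeze baseline residual scale: RSS from the accumulators
    cf <- engineCoefs(engine)
    rss <- engine@syy - cf$intercept * engine@sy - cf$slope * engine@sty
    df <- max(t - 2L, 1L)
    engine@baselineSD <- sqrt(pmax(rss, 0) / df)
  }
  if (length(engine@baselineSD)) {
    sd <- engine@baselineSD
    z <- ifelse(sd > 1e-8, resid / pmax(sd, 1e-8), 0)
  } else {
    z <- rep(0, length(y))  # baseline scale not yet defined
  }
  list(engine = engine,
       dmn = mean(z[engine@dmnPos]),
       cen = mean(z[engine@cenPos]),
       isBaseline = t <= engine@nBaseline)
}

#' Positive diametric activity
#'
#' The per-TR feedback metric: the CEN activation estimate minus the DMN
#' activation estimate, both in baseline-SD units. Positive PDA corresponds
#' to the target state (DMN below CEN) and moves the feedback dot upwards;
#' negative PDA moves it down.
#'
#' @param cenEstimate,dmnEstimate finite activation estimates.
#' @return PDA in baseline-SD units.
#' @examples
#' computePDA(2.0, 0.5)   #  1.5
#' computePDA(0.5, 2.0)   # -1.5 (dot moves down)
#' @export
computePDA <- function(cenEstimate, dmnEstimate) {
  stopIf(!is.finite(cenEstimate) || !is.finite(dmnEstimate),
         "activation estimates must be finite")
  cenEstimate - dmnEstimate
}

#' Initialise the staircase display state
#'
#' The display shows a white dot (radius 12 px) between a target circle above
#' (center at +1) and a circle below (center at -1), both of initial radius
#' 56 px, centers 472 px apart. Sustained positions within or beyond a circle
#' shrink that circle by 10\% (at most 5 times per run) and re-center the
#' dot.
#'
#' @param dotRadiusPx dot radius, pixels.
#' @param circleRadiusPx initial circle radius, pixels.
#' @param centerDistancePx distance between circle centers, pixels.
#' @param shrinkFactor multiplicative radius change per shrink.
#' @param shrinkTriggerTRs qualifying TRs accumulated to trigger a shrink.
#' @param maxShrinks per-circle shrink cap per run.
#' @param gain display gain converting PDA (baseline-SD units) to
#'   circle-center units per TR.
#' @return A \linkS4class{FeedbackState}.
#' @export
initFeedbackState <- function(dotRadiusPx = 12, circleRadiusPx = 56,
                              centerDistancePx = 472, shrinkFactor = 0.9,
                              shrinkTriggerTRs = 5, maxShrinks = 5,
                              gain = 0.1) {
  new("FeedbackState",
      dotY = 0,
      circleRadiusPx = c(upper = circleRadiusPx, lower = circleRadiusPx),
      accum = c(upper = 0, lower = 0),
      shrinkCount = c(upper = 0, lower = 0),
      events = data.frame(tr = integer(0), circle = character(0),
                          event = character(0)),
      pars = list(dotRadiusPx = dotRadiusPx, circleRadiusPx = circleRadiusPx,
                  centerDistancePx = centerDistancePx,
                  shrinkFactor = shrinkFactor,
                  shrinkTriggerTRs = shrinkTriggerTRs,
                  maxShrinks = maxShrinks, gain = gain))
}

#' Advance the staircase display by one TR
#'
#' Adds the new PDA value (times the display gain) to the dot ordinate. The
#' dot is "within or beyond" a circle when its center has passed the circle's
#' near edge — \code{dotY >= 1 - r} for the upper circle and
#' \code{dotY <= -(1 - r)} for the lower one, with the radius expressed in
#' circle-center units (pixels divided by half the center distance). A
#' qualifying TR increments that circle's accumulation counter; when the
#' counter reaches the trigger and the circle has shrunk fewer than the
#' maximum number of times, the radius shrinks by the shrink factor, the dot
#' is re-centered at 0 and the counter resets. At the cap, nothing changes.
#'
#' @param state a \linkS4class{FeedbackState}.
#' @param pda the new PDA value.
#' @param trIndex TR index recorded in the event log.
#' @return the updated \linkS4class{FeedbackState}.
#' @export
stepDisplay <- function(state, pda, trIndex = NA_integer_) {
  stopifnot(is(state, "FeedbackState"))
  stopIf(!is.finite(pda), "pda must be finite")
  p <- state@pars
  halfDist <- p$centerDistancePx / 2
  state@dotY <- state@dotY + pda * p$gain
  rUnits <- state@circleRadiusPx / halfDist
  inUpper <- state@dotY >= 1 - rUnits[["upper"]]
  inLower <- state@dotY <= -(1 - rUnits[["lower"]])
  for (nm in c("upper", "lower")) {
    hit <- if (nm == "upper") inUpper else inLower
    if (!hit) next
    state@accum[[nm]] <- state@accum[[nm]] + 1
    if (state@accum[[nm]] >= p$shrinkTriggerTRs) {
      if (state@shrinkCount[[nm]] < p$maxShrinks) {
        state@shrinkCount[[nm]] <- state@shrinkCount[[nm]] + 1
        state@circleRadiusPx[[nm]] <-
          p$circleRadiusPx * p$shrinkFactor^state@shrinkCount[[nm]]
        state@dotY <- 0
        state@accum[[nm]] <- 0
        state@events <- rbind(state@events,
                              data.frame(tr = as.integer(trIndex),
                                         circle = nm, event = "shrink"))
      }
      # at the cap the display is static: no shrink, no reset
    }
  }
  state
}

#' Stream a full run through the closed loop
#'
#' Feeds every volume of a series through the incremental GLM, computes the
#' PDA for post-baseline TRs, advances the staircase display, and summarises
#' the run. Time in target is the fraction of feedback (non-baseline) TRs
#' with PDA > 0, i.e. DMN activation below CEN activation.
#'
#' @param engine a freshly initialised \linkS4class{FeedbackEngine}.
#' @param series a \linkS4class{VolumeSeries}; must be longer than the
#'   engine's baseline block.
#' @param state optional initial \linkS4class{FeedbackState}; default
#'   \code{initFeedbackState()}.
#' @param lagTRs integer display lag between a volume's estimate and the dot
#'   update it drives (default 0).
#' @return A \linkS4class{RunResult}.
#' @export
runFeedbackRun <- function(engine, series, state = initFeedbackState(),
                           lagTRs = 0L) {
  stopifnot(is(engine, "FeedbackEngine"), is(series, "VolumeSeries"))
  tlen <- nVolumes(series)
  stopIf(tlen < engine@nBaseline + 1L,
         "series must be longer than the baseline block")
  dat <- volData(series)
  dmn <- cen <- pda <- dotY <- rep(NA_real_, tlen)
  isBase <- logical(tlen)
  pending <- numeric(0)   # PDA values waiting out the display lag
  for (t in seq_len(tlen)) {
    up <- updateEngine(engine, dat[, , , t, drop = TRUE])
    engine <- up$engine
    dmn[t] <- up$dmn; cen[t] <- up$cen; isBase[t] <- up$isBaseline
    if (!up$isBaseline) {
      pda[t] <- computePDA(up$cen, up$dmn)
      pending <- c(pending, pda[t])
      if (length(pending) > lagTRs) {
        state <- stepDisplay(state, pending[1L], trIndex = t)
        pending <- pending[-1L]
      }
    }
    dotY[t] <- state@dotY
  }
  fb <- !isBase
  tit <- mean(pda[fb] > 0)
  new("RunResult", dmn = dmn, cen = cen,
      pda = ifelse(fb, pda, NA_real_), dotY = dotY, baseline = isBase,
      events = state@events, timeInTarget = tit,
      nFeedbackTRs = sum(fb), finalState = state)
}

#' Group test of time in target against chance
#'
#' One-tailed one-sample t-test of per-subject time-in-target fractions
#' against the 50\% chance level.
#'
#' @param fractions per-subject time-in-target values (n >= 2).
#' @param alternative sidedness; default "greater" (more time in target than
#'   chance).
#' @return the \code{\link{oneSampleT}} report.
#' @export
groupTargetTest <- function(fractions, alternative = "greater") {
  stopIf(length(fractions) < 2L, "need at least 2 subjects")
  oneSampleT(fractions, mu = 0.5, alternative = alternative)
}
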