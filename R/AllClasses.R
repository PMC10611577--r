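#' @import methods
NULL

#' 4-D BOLD time series
#'
#' Container for a volumetric fMRI run: an X x Y x Z x T array together with
#' the repetition time and a voxel-to-world affine. Every imaging stage of the
#' package consumes and produces this class.
#'
#' @slot data 4-D numeric array (X x Y x Z x T), arbitrary signal units.
#' @slot tr repetition time in seconds.
#' @slot affine 4 x 4 voxel-to-world matrix (mm); by default a diagonal
#'   voxel-size matrix.
#' @export
setClass("VolumeSeries",
  representation(data = "array", tr = "numeric", affine = "matrix"))

setValidity("VolumeSeries", function(object) {
  if (length(dim(object@data)) != 4L) return("data must be a 4-D array")
  if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
    return("tr must be a single positive number")
  if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4 x 4")
  TRUE
})

#' Construct a VolumeSeries
#'
#' @param data 4-D numeric array (X x Y x Z x T).
#' @param tr repetition time, seconds.
#' @param affine 4 x 4 voxel-to-world matrix; default a diagonal matrix built
#'   from \code{voxelSize}.
#' @param voxelSize voxel edge lengths in mm used for the default affine.
#' @return A \linkS4class{VolumeSeries}.
#' @export
VolumeSeries <- function(data, tr, affine = NULL, voxelSize = c(2, 2, 2)) {
  if (is.null(affine)) affine <- diag(c(voxelSize, 1))
  new("VolumeSeries", data = data, tr = as.numeric(tr), affine = affine)
}

#' Binary network-of-interest mask
#'
#' A binary 3-D field labelling one network of interest (e.g. DMN or CEN),
#' with provenance: the source decomposition component and its template-match
#' correlation.
#'
#' @slot mask logical 3-D array.
#' @slot label network label, e.g. "DMN" or "CEN".
#' @slot sourceComponent index of the component the mask was derived from.
#' @slot matchR spatial correlation with the matched template.
#' @export
setClass("NetworkMask",
  representation(mask = "array", label = "character",
                 sourceComponent = "integer", matchR = "numeric"))

setValidity("NetworkMask", function(object) {
  if (length(dim(object@mask)) != 3L) return("mask must be a 3-D array")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (length(object@label) != 1L) return("label must be a single string")
  TRUE
})

#' Construct a NetworkMask
#'
#' @param mask logical or 0/1 3-D array.
#' @param label network label.
#' @param sourceComponent optional source component index.
#' @param matchR optional template-match correlation.
#' @return A \linkS4class{NetworkMask}.
#' @export
NetworkMask <- function(mask, label,
                        sourceComponent = NA_integer_, matchR = NA_real_) {
  m <- array(as.logical(mask), dim = dim(mask))
  new("NetworkMask", mask = m, label = as.character(label),
      sourceComponent = as.integer(sourceComponent),
      matchR = as.numeric(matchR))
}

#' Spatial decomposition result
#'
#' Spatial maps and associated timecourses from a source-separation
#' decomposition of a concatenated run, restricted to in-brain voxels.
#'
#' @slot maps 4-D array (X x Y x Z x K) of component loadings.
#' @slot timecourses T x K matrix of component timecourses.
#' @slot brainMask logical 3-D array of the voxels that entered the
#'   decomposition.
#' @export
setClass("ComponentSet",
  representation(maps = "array", timecourses = "matrix", brainMask = "array"))

setValidity("ComponentSet", function(object) {
  if (length(dim(object@maps)) != 4L) return("maps must be 4-D (x,y,z,k)")
  if (dim(object@maps)[4L] != ncol(object@timecourses))
    return("number of maps must equal number of timecourses")
  TRUE
})

#' Confound set for denoising
#'
#' Motion parameters and derived nuisance series for one run.
#'
#' @slot motion T x 6 matrix: translations (mm) then rotations (radians).
#' @slot fd framewise displacement series (mm), fd[1] = 0.
#' @slot globalSignalZ z-scored global (in-brain mean) signal.
#' @slot outliers logical flags for scrubbed frames.
#' @slot compcorWM T x k matrix of white-matter aCompCor components.
#' @slot compcorCSF T x k matrix of CSF aCompCor components.
#' @export
setClass("ConfoundSet",
  representation(motion = "matrix", fd = "numeric", globalSignalZ = "numeric",
                 outliers = "logical", compcorWM = "matrix",
                 compcorCSF = "matrix"))

#' Construct a ConfoundSet
#'
#' Any component other than \code{motion} may be omitted; empty defaults of
#' matching length are filled in.
#'
#' @param motion T x 6 matrix of realignment parameters.
#' @param fd framewise displacement; computed from \code{motion} if missing.
#' @param globalSignalZ z-scored global signal (optional).
#' @param outliers logical outlier flags (optional).
#' @param compcorWM,compcorCSF aCompCor component matrices (optional).
#' @return A \linkS4class{ConfoundSet}.
#' @export
ConfoundSet <- function(motion, fd = NULL, globalSignalZ = NULL,
                        outliers = NULL, compcorWM = NULL, compcorCSF = NULL) {
  motion <- as.matrix(motion)
  tlen <- nrow(motion)
  if (is.null(fd)) fd <- framewiseDisplacement(motion)
  if (is.null(globalSignalZ)) globalSignalZ <- rep(0, tlen)
  if (is.null(outliers)) outliers <- rep(FALSE, tlen)
  if (is.null(compcorWM)) compcorWM <- matrix(0, tlen, 0)
  if (is.null(compcorCSF)) compcorCSF <- matrix(0, tlen, 0)
  new("ConfoundSet", motion = motion, fd = as.numeric(fd),
      globalSignalZ = as.numeric(globalSignalZ),
      outliers = as.logical(outliers),
      compcorWM = as.matrix(compcorWM), compcorCSF = as.matrix(compcorCSF))
}

setValidity("ConfoundSet", function(object) {
  tlen <- nrow(object@motion)
  if (ncol(object@motion) != 6L) return("motion must have 6 columns")
  if (length(object@fd) != tlen) return("fd length must match motion rows")
  if (length(object@outliers) != tlen) return("outliers length mismatch")
  if (any(object@fd < 0)) return("fd must be non-negative")
  TRUE
})

#' Spherical seed specification
#'
#' @slot center 3-vector, world (mm) coordinates of the sphere center.
#' @slot radius sphere radius in mm.
#' @slot label seed label, e.g. "sgACC" or "MPFC".
#' @export
setClass("SeedSpec",
  representation(center = "numeric", radius = "numeric", label = "character"))

#' Construct a SeedSpec
#'
#' @param center world-space center (mm), length 3.
#' @param radius radius in mm (default 8, the conventional seed size).
#' @param label seed label.
#' @return A \linkS4class{SeedSpec}.
#' @export
SeedSpec <- function(center, radius = 8, label = "seed") {
  stopIf(length(center) != 3L, "center must have length 3")
  stopIf(radius <= 0, "radius must be positive")
  new("SeedSpec", center = as.numeric(center), radius = as.numeric(radius),
      label = as.character(label))
}

#' Seed connectivity map
#'
#' Voxelwise Fisher-z connectivity with a seed timecourse.
#'
#' @slot z 3-D array of Fisher-z values (finite everywhere reported).
#' @slot seed the \linkS4class{SeedSpec} used (may carry label only).
#' @slot nUsableVols number of volumes entering the correlation.
#' @slot degenerate logical 3-D array flagging zero-variance voxels whose z
#'   was set to 0.
#' @export
setClass("ConnectivityMap",
  representation(z = "array", seed = "SeedSpec", nUsableVols = "integer",
                 degenerate = "array"))

setValidity("ConnectivityMap", function(object) {
  if (length(dim(object@z)) != 3L) return("z must be 3-D")
  if (any(!is.finite(object@z))) return("fisher z field must be finite")
  TRUE
})

#' Adaptive staircase display state
#'
#' The visual feedback state machine: a white dot on a vertical axis between
#' an upper (target) and a lower circle. Dot ordinate is expressed in
#' circle-center units (upper circle center at +1, lower at -1); pixel
#' distances convert through half the inter-center distance.
#'
#' @slot dotY dot ordinate, circle-center units.
#' @slot circleRadiusPx named numeric, current radii (pixels) of
#'   \code{upper} and \code{lower} circles.
#' @slot accum named numeric, qualifying-TR counters since last shrink.
#' @slot shrinkCount named numeric, shrink events so far (capped).
#' @slot events data.frame log of (tr, circle, event).
#' @slot pars named list of display constants (dot radius, initial radius,
#'   center distance, shrink factor, trigger count, cap, gain).
#' @export
setClass("FeedbackState",
  representation(dotY = "numeric", circleRadiusPx = "numeric",
                 accum = "numeric", shrinkCount = "numeric",
                 events = "data.frame", pars = "list"))

setValidity("FeedbackState", function(object) {
  p <- object@pars
  for (nm in c("upper", "lower")) {
    if (object@shrinkCount[[nm]] > p$maxShrinks)
      return("shrink count exceeds cap")
    expected <- p$circleRadiusPx * p$shrinkFactor^object@shrinkCount[[nm]]
    if (abs(object@circleRadiusPx[[nm]] - expected) > 1e-9)
      return("circle radius inconsistent with shrink count")
  }
  TRUE
})

#' Incremental GLM feedback engine
#'
#' Running accumulators sufficient to solve, at every TR, the per-voxel
#' ordinary least squares of signal on an intercept and a linear drift term,
#' restricted to the DMN/CEN mask voxels. Baseline residual statistics are
#' frozen when the baseline block ends and define the activation scale.
#'
#' Functional updates: \code{updateEngine()} returns a new engine.
#'
#' @slot dims grid dimensions of the expected volumes.
#' @slot voxIdx flat indices of all tracked voxels (union of masks).
#' @slot dmnPos,cenPos positions within \code{voxIdx} of the DMN-only and
#'   CEN-only voxels (overlap voxels belong to neither summary).
#' @slot n number of volumes seen.
#' @slot st,stt scalars: running sums of t and t^2.
#' @slot sy,sty,syy per-voxel running sums of y, t*y, y^2.
#' @slot nBaseline baseline length in volumes.
#' @slot tr repetition time, seconds.
#' @slot baselineSD frozen per-voxel baseline residual SD (empty until the
#'   baseline block completes).
#' @export
setClass("FeedbackEngine",
  representation(dims = "integer", voxIdx = "integer",
                 dmnPos = "integer", cenPos = "integer",
                 n = "integer", st = "numeric", stt = "numeric",
                 sy = "numeric", sty = "numeric", syy = "numeric",
                 nBaseline = "integer", tr = "numeric",
                 baselineSD = "numeric"))

#' Result of one neurofeedback run
#'
#' @slot dmn,cen per-TR network activation estimates, baseline-SD units.
#' @slot pda per-TR positive diametric activity (CEN minus DMN estimate).
#' @slot dotY per-TR dot ordinate, circle-center units.
#' @slot baseline logical per-TR flags for baseline volumes.
#' @slot events shrink-event log.
#' @slot timeInTarget fraction of feedback TRs with PDA > 0.
#' @slot nFeedbackTRs number of non-baseline TRs.
#' @slot finalState final \linkS4class{FeedbackState}.
#' @export
setClass("RunResult",
  representation(dmn = "numeric", cen = "numeric", pda = "numeric",
                 dotY = "numeric", baseline = "logical",
                 events = "data.frame", timeInTarget = "numeric",
                 nFeedbackTRs = "integer", finalState = "FeedbackState"))

setValidity("RunResult", function(object) {
  fb <- !object@baseline
  if (any(abs(object@pda[fb] -
              (object@cen[fb] - object@dmn[fb])) > 1e-12, na.rm = TRUE))
    return("pda must equal cen - dmn at every feedback TR")
  TRUE
})

#' Mediation analysis result
#'
#' Unstandardized and standardized paths a (X -> M), b (M -> Y | X),
#' c (total X -> Y) and c' (direct X -> Y | M), with the Sobel test of the
#' indirect effect a*b.
#'
#' @slot paths data.frame with one row per path (c, a, b, c_prime) and
#'   columns b, beta, se, t, df, p.
#' @slot sobelZ Sobel statistic (delta-method z for the indirect effect).
#' @slot sobelP two-tailed normal p for the Sobel statistic.
#' @slot n sample size.
#' @export
setClass("MediationResult",
  representation(paths = "data.frame", sobelZ = "numeric",
                 sobelP = "numeric", n = "integer"))

setValidity("MediationResult", function(object) {
  b <- function(p) object@paths[object@paths$path == p, "beta"]
  if (abs(b("c") - (b("a") * b("b") + b("c_prime"))) > 1e-8)
    return("standardized decomposition beta_c = beta_a*beta_b + beta_c' violated")
  TRUE
})

#' Simulated behavioral cohort
#'
#' Three standardized variables per subject following the mediation chain
#' X (neurofeedback performance) -> M (connectivity change) -> Y (state
#' mindfulness change), with the generating path coefficients retained.
#'
#' @slot data data.frame with columns nf_performance, conn_change, sms_change.
#' @slot truePaths named numeric: a, b, c_prime used in generation.
#' @slot seed the seed used.
#' @export
setClass("BehaviorCohort",
  representation(data = "data.frame", truePaths = "numeric", seed = "integer"))

setValidity("BehaviorCohort", function(object) {
  need <- c("nf_performance", "conn_change", "sms_change")
  if (!all(need %in% names(object@data)))
    return("cohort must contain nf_performance, conn_change, sms_change")
  TRUE
})
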