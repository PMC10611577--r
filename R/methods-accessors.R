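# accessor and show methods

#' @rdname VolumeSeries-class
#' @export
setMethod("volData", "VolumeSeries", function(x) x@data)
#' @rdname VolumeSeries-class
#' @export
setMethod("repetitionTime", "VolumeSeries", function(x) x@tr)
#' @rdname VolumeSeries-class
#' @export
setMethod("voxelAffine", "VolumeSeries", function(x) x@affine)
#' @rdname VolumeSeries-class
#' @export
setMethod("nVolumes", "VolumeSeries", function(x) dim(x@data)[4L])
#' @rdname VolumeSeries-class
#' @export
setMethod("gridDims", "VolumeSeries", function(x) dim(x@data)[1:3])

setMethod("show", "VolumeSeries", function(object) {
  d <- dim(object@data)
  cat("VolumeSeries:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4L], "volumes, TR =", object@tr, "s\n")
})

#' @rdname NetworkMask-class
#' @export
setMethod("maskArray", "NetworkMask", function(x) x@mask)
#' @rdname NetworkMask-class
#' @export
setMethod("voxelCount", "NetworkMask", function(x) sum(x@mask))
#' @rdname NetworkMask-class
#' @export
setMethod("networkLabel", "NetworkMask", function(x) x@label)

setMethod("show", "NetworkMask", function(object) {
  cat(sprintf("NetworkMask '%s': %d voxels (component %s, match r = %s)\n",
              object@label, sum(object@mask),
              ifelse(is.na(object@sourceComponent), "NA",
                     object@sourceComponent),
              ifelse(is.na(object@matchR), "NA",
                     format(object@matchR, digits = 3))))
})

#' @rdname ComponentSet-class
#' @export
setMethod("nComponents", "ComponentSet", function(x) dim(x@maps)[4L])
#' @rdname ComponentSet-class
#' @export
setMethod("componentMap", "ComponentSet", function(x, i) {
  x@maps[, , , i, drop = TRUE]
})
#' @rdname ComponentSet-class
#' @export
setMethod("componentTimecourses", "ComponentSet", function(x) x@timecourses)

setMethod("show", "ComponentSet", function(object) {
  cat("ComponentSet:", dim(object@maps)[4L], "components on a",
      paste(dim(object@maps)[1:3], collapse = " x "), "grid,",
      nrow(object@timecourses), "timepoints\n")
})

#' @rdname ConnectivityMap-class
#' @export
setMethod("zMap", "ConnectivityMap", function(x) x@z)

setMethod("show", "ConnectivityMap", function(object) {
  cat(sprintf("ConnectivityMap (seed '%s'): %s grid, %d usable volumes, z range [%.3f, %.3f]\n",
              object@seed@label, paste(dim(object@z), collapse = " x "),
              object@nUsableVols, min(object@z), max(object@z)))
})

#' @rdname RunResult-class
#' @export
setMethod("timeInTarget", "RunResult", function(x) x@timeInTarget)
#' @rdname RunResult-class
#' @export
setMethod("pdaTrace", "RunResult", function(x) x@pda)

setMethod("show", "RunResult", function(object) {
  cat(sprintf("RunResult: %d TRs (%d feedback), time in target = %.3f, %d shrink events\n",
              length(object@pda), object@nFeedbackTRs, object@timeInTarget,
              nrow(object@events)))
})

#' @rdname MediationResult-class
#' @export
setMethod("mediationPaths", "MediationResult", function(x) x@paths)
#' @rdname MediationResult-class
#' @export
setMethod("sobelZ", "MediationResult", function(x) x@sobelZ)

setMethod("show", "MediationResult", function(object) {
  cat("Mediation analysis (n =", object@n, ")\n")
  print(format(object@paths, digits = 3), row.names = FALSE)
  cat(sprintf("Sobel z = %.3f, two-tailed p = %.4f\n",
              object@sobelZ, object@sobelP))
})

#' @rdname BehaviorCohort-class
#' @export
setMethod("cohortData", "BehaviorCohort", function(x) x@data)

setMethod("show", "BehaviorCohort", function(object) {
  cat(sprintf("BehaviorCohort: n = %d subjects; true paths a = %.2f, b = %.2f, c' = %.2f\n",
              nrow(object@data), object@truePaths[["a"]],
              object@truePaths[["b"]], object@truePaths[["c_prime"]]))
})

setMethod("show", "FeedbackState", function(object) {
  cat(sprintf("FeedbackState: dot y = %.3f; radii (px) upper %.2f / lower %.2f; shrinks %d / %d\n",
              object@dotY, object@circleRadiusPx[["upper"]],
              object@circleRadiusPx[["lower"]],
              as.integer(object@shrinkCount[["upper"]]),
              as.integer(object@shrinkCount[["lower"]])))
})

setMethod("show", "FeedbackEngine", function(object) {
  cat(sprintf("FeedbackEngine: %d tracked voxels (%d DMN, %d CEN), %d/%d volumes seen%s\n",
              length(object@voxIdx), length(object@dmnPos),
              length(object@cenPos), object@n, object@nBaseline,
              if (length(object@baselineSD)) ", baseline frozen" else ""))
})
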