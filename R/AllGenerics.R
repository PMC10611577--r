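#' @rdname VolumeSeries-class
#' @param object,x a VolumeSeries
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname VolumeSeries-class
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))
#' @rdname VolumeSeries-class
#' @export
setGeneric("voxelAffine", function(x) standardGeneric("voxelAffine"))
#' @rdname VolumeSeries-class
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))
#' @rdname VolumeSeries-class
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' @rdname NetworkMask-class
#' @param x a NetworkMask
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @rdname NetworkMask-class
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))
#' @rdname NetworkMask-class
#' @export
setGeneric("networkLabel", function(x) standardGeneric("networkLabel"))

#' @rdname ComponentSet-class
#' @param x a ComponentSet
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))
#' @rdname ComponentSet-class
#' @param i component index
#' @export
setGeneric("componentMap", function(x, i) standardGeneric("componentMap"))
#' @rdname ComponentSet-class
#' @export
setGeneric("componentTimecourses",
           function(x) standardGeneric("componentTimecourses"))

#' @rdname ConnectivityMap-class
#' @param x a ConnectivityMap
#' @export
setGeneric("zMap", function(x) standardGeneric("zMap"))

#' @rdname RunResult-class
#' @param x a RunResult
#' @export
setGeneric("timeInTarget", function(x) standardGeneric("timeInTarget"))
#' @rdname RunResult-class
#' @export
setGeneric("pdaTrace", function(x) standardGeneric("pdaTrace"))

#' @rdname MediationResult-class
#' @param x a MediationResult
#' @export
setGeneric("mediationPaths", function(x) standardGeneric("mediationPaths"))
#' @rdname MediationResult-class
#' @export
setGeneric("sobelZ", function(x) standardGeneric("sobelZ"))

#' @rdname BehaviorCohort-class
#' @param x a BehaviorCohort
#' @export
setGeneric("cohortData", function(x) standardGeneric("cohortData"))
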