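# Single source of truth for every paradigm constant. paradigmConfig() and
# every stage default draw from this list; stage code never restates a
# constant.
.paradigmDefaults <- list(
  tr = 1.2,                     # s, repetition time of the feedback EPI
  baselineSec = 30,             # s, crosshair rest before feedback
  runSec = 150,                 # s, one neurofeedback run (2.5 min)
  nRuns = 5,                    # back-to-back feedback runs
  restSec = 300,                # s, each pre/post resting run (5 min)
  dotRadiusPx = 12,             # px, feedback dot radius
  circleRadiusPx = 56,          # px, initial circle radius
  centerDistancePx = 472,       # px, distance between circle centers
  shrinkFactor = 0.9,           # per-shrink radius multiplier
  shrinkTriggerTRs = 5,         # qualifying TRs per shrink
  maxShrinks = 5,               # per-circle cap per run
  topFraction = 0.10,           # localizer binarization fraction
  nComponents = 30,             # decomposition dimensionality
  bandHz = c(0.008, 0.09),      # Hz, denoising pass band
  fdThreshMm = 0.9,             # mm, lenient FD outlier threshold
  gsZThresh = 5,                # lenient global-signal z threshold
  fdrQ = 0.05,                  # small-volume FDR level
  displayGain = 0.1,            # PDA (SD units) -> circle-center units
  rngSeed = 1,
  seedSpecs = list(
    sgACC = list(center = c(-2, 22, -16), radius = 8),
    MPFC  = list(center = c(-1, 53, -3), radius = 8))
)

# field -> c(min, max) validation ranges
.paradigmRanges <- list(
  tr = c(0.1, 10), baselineSec = c(2, 600), runSec = c(10, 3600),
  nRuns = c(1, 100), restSec = c(10, 3600), dotRadiusPx = c(1, 1000),
  circleRadiusPx = c(1, 1000), centerDistancePx = c(2, 10000),
  shrinkFactor = c(0.01, 1), shrinkTriggerTRs = c(1, 1000),
  maxShrinks = c(0, 1000), topFraction = c(1e-6, 1 - 1e-6),
  nComponents = c(2, 1000), fdThreshMm = c(0.01, 100),
  gsZThresh = c(0.1, 100), fdrQ = c(1e-6, 1), displayGain = c(1e-6, 100),
  rngSeed = c(0, .Machine$integer.max)
)

#' Paradigm configuration
#'
#' A validated container for every constant of the neurofeedback paradigm
#' and analysis: timing (TR 1.2 s, 30-s baseline, 150-s runs, 5 runs,
#' 5-min rest runs), display geometry (12-px dot, 56-px circles, 472-px
#' center distance), staircase rules (10\% shrink, 5-TR trigger, 5-shrink
#' cap), localizer settings (30 components, top 10\%), denoising
#' (0.008-0.09 Hz band, FD > 0.9 mm / global-signal z > 5 outliers), the
#' FDR level, the display gain and the seed sphere specifications.
#'
#' @slot values named list of validated parameters.
#' @export
setClass("ParadigmConfig", representation(values = "list"))

setValidity("ParadigmConfig", function(object) {
  v <- object@values
  unknown <- setdiff(names(v), names(.paradigmDefaults))
  if (length(unknown))
    return(paste("unknown config field(s):", paste(unknown, collapse = ", ")))
  missing <- setdiff(names(.paradigmDefaults), names(v))
  if (length(missing))
    return(paste("missing config field(s):", paste(missing, collapse = ", ")))
  for (nm in names(.paradigmRanges)) {
    rng <- .paradigmRanges[[nm]]
    val <- v[[nm]]
    if (!is.numeric(val) || any(!is.finite(val)) ||
        any(val < rng[1L]) || any(val > rng[2L]))
      return(sprintf("config field '%s' outside [%g, %g]",
                     nm, rng[1L], rng[2L]))
  }
  if (length(v$bandHz) != 2L || v$bandHz[1L] <= 0 ||
      v$bandHz[1L] >= v$bandHz[2L])
    return("bandHz must be an increasing positive pair")
  for (s in v$seedSpecs)
    if (length(s$center) != 3L || s$radius <= 0)
      return("seedSpecs entries need a 3-vector center and positive radius")
  TRUE
})

setMethod("show", "ParadigmConfig", function(object) {
  v <- object@values
  cat(sprintf("ParadigmConfig: TR %.3g s, baseline %g s, %d runs x %g s; band %g-%g Hz; top %.0f%%\n",
              v$tr, v$baselineSec, as.integer(v$nRuns), v$runSec,
              v$bandHz[1L], v$bandHz[2L], 100 * v$topFraction))
})

#' Construct a paradigm configuration
#'
#' Returns the default configuration, optionally overriding named fields.
#' Unknown fields and out-of-range values are rejected at construction.
#'
#' @param ... named overrides of default fields.
#' @return A \linkS4class{ParadigmConfig}.
#' @examples
#' cfg <- paradigmConfig(displayGain = 0.2)
#' cfgGet(cfg, "tr")
#' @export
paradigmConfig <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.paradigmDefaults))
  stopIf(length(unknown) > 0,
         paste("unknown config field(s):", paste(unknown, collapse = ", ")))
  v <- utils::modifyList(.paradigmDefaults, over)
  new("ParadigmConfig", values = v)
}

#' @rdname paradigmConfig
#' @param config a \linkS4class{ParadigmConfig}.
#' @param field field name.
#' @export
cfgGet <- function(config, field) {
  stopifnot(is(config, "ParadigmConfig"))
  stopIf(!field %in% names(config@values),
         paste("unknown config field:", field))
  config@values[[field]]
}

#' Load a configuration file
#'
#' Reads a YAML or JSON configuration (by file extension), fills unspecified
#' fields with the paradigm defaults, rejects unknown keys, and validates
#' every numeric field against its documented range. An empty file yields
#' the full default configuration.
#'
#' @param path file path (.yaml/.yml or .json).
#' @return A \linkS4class{ParadigmConfig}.
#' @export
loadConfig <- function(path) {
  stopIf(!file.exists(path), paste("no such config file:", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be .yaml/.yml or .json", call. = FALSE)
  if (is.null(raw)) raw <- list()
  for (nm in names(raw))
    if (nm != "seedSpecs" && is.numeric(raw[[nm]]))
      raw[[nm]] <- as.numeric(raw[[nm]])
  if (!is.null(raw$seedSpecs))
    raw$seedSpecs <- lapply(raw$seedSpecs, function(s)
      list(center = as.numeric(s$center), radius = as.numeric(s$radius)))
  do.call(paradigmConfig, raw)
}

#' Save a configuration file
#'
#' Serializes a configuration to YAML or JSON with full numeric precision so
#' that a save/load round trip reproduces the configuration exactly.
#'
#' @param config a \linkS4class{ParadigmConfig}.
#' @param path destination path (.yaml/.yml or .json).
#' @return \code{path}, invisibly.
#' @export
saveConfig <- function(config, path) {
  stopifnot(is(config, "ParadigmConfig"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(config@values, path, precision = 17L)
  } else if (ext == "json") {
    jsonlite::write_json(config@values, path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else stop("config must be .yaml/.yml or .json", call. = FALSE)
  invisible(path)
}
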