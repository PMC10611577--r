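#' Run a full synthetic neurofeedback session cohort
#'
#' End-to-end integration of every stage on synthetic data, mirroring the
#' session order of a neurofeedback visit: per subject, a localizer run is
#' decomposed and personalized DMN/CEN masks are built; five feedback runs
#' stream through the incremental-GLM engine and staircase; pre- and
#' post-feedback resting runs (with a planted, performance-dependent
#' reduction in coupling between a subgenual-cingulate-like seed region and a
#' medial-prefrontal-like region) are denoised and seed connectivity maps
#' computed. At the group level the pipeline reports the time-in-target test
#' against chance, the pre/post connectivity change under small-volume FDR,
#' the brain-behavior correlations, the mediation analysis
#' (performance -> connectivity change -> state-mindfulness change) and the
#' session-to-session reliability (ICC) of within-network connectivity.
#'
#' Problem sizes are deliberately scaled down (small grids, shortened rest
#' runs) so a full cohort runs in seconds; the paradigm constants themselves
#' come from \code{config}.
#'
#' @param config a \linkS4class{ParadigmConfig}.
#' @param seed integer master seed; every stage derives its randomness from
#'   it, so the same seed reproduces the session exactly.
#' @param nSubjects cohort size (default 9).
#' @param gridDims synthetic grid (default 20 x 20 x 10).
#' @param nLocalizerVols,nRestVols scaled lengths of the localizer and rest
#'   runs in volumes (the rest default of 250 volumes is the full 5-min run
#'   at TR 1.2 s; it also keeps the pass band well-resolved for denoising).
#' @param nComponentsSession decomposition dimensionality for the scaled
#'   grids (the full-size default of 30 components needs full-size data).
#' @param outdir optional directory; when given, NIfTI masks, TSV confound
#'   and trace tables, the cohort CSV and a JSON summary are written there.
#' @return list: \code{subjects} (per-subject data.frame), \code{targetTest},
#'   \code{prepost} (small-volume FDR result), \code{corPerfConn},
#'   \code{corConnSms}, \code{mediation}, \code{icc}, \code{config},
#'   \code{seed}.
#' @export
runSession <- function(config = paradigmConfig(), seed = NULL,
                       nSubjects = 9, gridDims = c(20, 20, 10),
                       nLocalizerVols = 120, nRestVols = 250,
                       nComponentsSession = 6, outdir = NULL) {
  stopifnot(is(config, "ParadigmConfig"))
  if (is.null(seed)) seed <- cfgGet(config, "rngSeed")
  tr <- cfgGet(config, "tr")
  nRunVols <- round(cfgGet(config, "runSec") / tr)
  nRuns <- cfgGet(config, "nRuns")
  affine <- diag(c(2, 2, 2, 1))
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)

  subj <- vector("list", nSubjects)
  preMapsAll <- postMapsAll <- vector("list", nSubjects)
  regionMask <- NULL
  # one network geometry for the whole cohort: subjects are analysed in a
  # common (template) space, as after spatial normalization
  maps <- makeNetworkMaps(gridDims, 2, 3, seed = subSeed(seed, 1L))
  names(maps) <- c("DMN", "CEN")
  for (i in seq_len(nSubjects)) {

    # --- localizer: decompose, match to templates, binarize top 10% ---
    tcLoc <- networkTimecourses(nLocalizerVols, 2, betweenR = -0.3,
                                seed = subSeed(seed, i * 10L + 1L))
    loc <- simulateRun(lapply(maps, function(m) 3 * m), tcLoc,
                       driftSlope = 0.02, noiseSd = 1, tr = tr,
                       seed = subSeed(seed, i * 10L + 2L))
    masks <- localizeNetworks(loc$series, templates = maps,
                              nComponents = nComponentsSession,
                              topFraction = cfgGet(config, "topFraction"),
                              brainMask = array(TRUE, gridDims),
                              seed = subSeed(seed, i * 10L + 3L))

    # --- five feedback runs with subject-specific episodic engagement ---
    duty <- withSeed(subSeed(seed, i * 10L + 4L),
                     min(max(stats::rnorm(1, mean = 0.62, sd = 0.06),
                             0.45), 0.8))
    nBase <- ceiling(cfgGet(config, "baselineSec") / tr)
    tits <- numeric(nRuns)
    runs <- vector("list", nRuns)
    for (r in seq_len(nRuns)) {
      fb <- simulateFeedbackSeries(masks$DMN, masks$CEN, nVols = nRunVols,
                                   nBaselineVols = nBase, amplitude = 1.5,
                                   engagementProb = duty, noiseSd = 1,
                                   tr = tr,
                                   seed = subSeed(seed, i * 10L + 4L) + r)
      eng <- initEngine(masks$DMN, masks$CEN, tr = tr,
                        nBaselineVols = nBase)
      st <- initFeedbackState(
        dotRadiusPx = cfgGet(config, "dotRadiusPx"),
        circleRadiusPx = cfgGet(config, "circleRadiusPx"),
        centerDistancePx = cfgGet(config, "centerDistancePx"),
        shrinkFactor = cfgGet(config, "shrinkFactor"),
        shrinkTriggerTRs = cfgGet(config, "shrinkTriggerTRs"),
        maxShrinks = cfgGet(config, "maxShrinks"),
        gain = cfgGet(config, "displayGain"))
      runs[[r]] <- runFeedbackRun(eng, fb$series, state = st)
      tits[r] <- timeInTarget(runs[[r]])
    }
    perfLast <- tits[nRuns]
    perfMean <- mean(tits)

    # --- pre/post rest with performance-dependent coupling reduction ---
    # seed region: peak blob of the DMN field; target region: a second,
    # disjoint high-loading DMN region
    dmnIdx <- order(-maps$DMN, seq_along(maps$DMN))
    seedRegion <- array(FALSE, gridDims); seedRegion[dmnIdx[1:30]] <- TRUE
    rest <- setdiff(which(maps$DMN > 0.3 * max(maps$DMN)), dmnIdx[1:30])
    targetRegion <- array(FALSE, gridDims)
    targetRegion[rest[seq_len(min(60, length(rest)))]] <- TRUE
    if (is.null(regionMask)) regionMask <- targetRegion

    # stable per-subject coupling trait (drives test-retest reliability)
    couplingPre <- withSeed(subSeed(seed, i * 10L + 9L),
                            min(max(stats::rnorm(1, 0.85, 0.1), 0.3), 0.98))
    dCoup <- withSeed(subSeed(seed, i * 10L + 5L),
                      0.15 + 0.6 * (perfLast - 0.55) +
                        stats::rnorm(1, sd = 0.03))
    couplingPost <- min(max(couplingPre - dCoup, 0), 0.98)
    restTriplet <- withSeed(subSeed(seed, i * 10L + 6L),
      lapply(c(sess1 = couplingPre, pre = couplingPre,
               post = couplingPost),
                       function(coup) {
      runTag <- sample.int(100000L, 1L)  # caller seeds the stream
      tcs <- networkTimecourses(nRestVols, 2, betweenR = 0,
                                type = "lowfreq", seed = runTag, tr = tr,
                                band = cfgGet(config, "bandHz"))
      shared <- tcs[, 1L]
      distinct <- tcs[, 2L]
      fld <- list(seed = array(as.numeric(seedRegion), gridDims),
                  tgt = array(as.numeric(targetRegion), gridDims))
      tcm <- cbind(2 * shared,
                   2 * (coup * shared + sqrt(1 - coup^2) * distinct))
      simulateRun(fld, tcm, driftSlope = 0.03, noiseSd = 1, tr = tr,
                  seed = runTag + 1L)
    }))
    restPair <- restTriplet[c("pre", "post")]

    # confounds + denoising for both rest runs
    tissueWM <- array(FALSE, gridDims); tissueWM[, 1:2, ] <- TRUE
    tissueCSF <- array(FALSE, gridDims)
    tissueCSF[, (gridDims[2L] - 1L):gridDims[2L], ] <- TRUE
    fdMeans <- numeric(2)
    connMaps <- vector("list", 2)
    for (p in 1:2) {
      mot <- simulateMotion(nRestVols, spikeProb = 0.02, spikeScale = 1.5,
                            seed = subSeed(seed, i * 10L + 8L) + p)
      fd <- framewiseDisplacement(mot$params)
      fl <- flagOutliers(restPair[[p]]$series, fd,
                         gsThresh = cfgGet(config, "gsZThresh"),
                         fdThresh = cfgGet(config, "fdThreshMm"))
      conf <- ConfoundSet(mot$params, fd = fd,
                          globalSignalZ = fl$globalSignalZ,
                          outliers = fl$outliers,
                          compcorWM = compcorComponents(restPair[[p]]$series,
                                                        tissueWM),
                          compcorCSF = compcorComponents(
                            restPair[[p]]$series, tissueCSF))
      den <- denoiseSeries(restPair[[p]]$series, conf,
                           band = cfgGet(config, "bandHz"))
      fdMeans[p] <- mean(fd)
      connMaps[[p]] <- seedConnectivity(
        den, seedRegion,
        seed = SeedSpec(as.numeric(affine %*%
                          c(arrayInd(dmnIdx[1L], gridDims) - 1L, 1))[1:3],
                        radius = 8, label = "sgACC"))
      if (!is.null(outdir))
        writeConfoundsTSV(conf, file.path(outdir,
          sprintf("sub-%02d_%s_confounds.tsv", i,
                  c("pre", "post")[p])))
    }
    preMapsAll[[i]] <- connMaps[[1L]]
    postMapsAll[[i]] <- connMaps[[2L]]
    connChange <- mean(zMap(connMaps[[2L]])[targetRegion]) -
      mean(zMap(connMaps[[1L]])[targetRegion])

    # session-to-session within-network connectivity (reliability input)
    rois <- list(seedRegion, targetRegion)
    wnc1 <- withinNetworkConnectivity(restTriplet$sess1$series, rois)
    wnc2 <- withinNetworkConnectivity(restPair$pre$series, rois)

    subj[[i]] <- data.frame(
      subject = i, tit_last = perfLast, tit_mean = perfMean,
      conn_change = connChange, fd_pre = fdMeans[1L], fd_post = fdMeans[2L],
      dmn_voxels = voxelCount(masks$DMN), cen_voxels = voxelCount(masks$CEN),
      dmn_match_r = masks$DMN@matchR, cen_match_r = masks$CEN@matchR,
      wnc_session1 = wnc1, wnc_session2 = wnc2)

    if (!is.null(outdir)) {
      writeMask(masks$DMN, file.path(outdir,
        sprintf("sub-%02d_dmn_mask.nii.gz", i)))
      writeMask(masks$CEN, file.path(outdir,
        sprintf("sub-%02d_cen_mask.nii.gz", i)))
      writeRunTrace(runs[[nRuns]], file.path(outdir,
        sprintf("sub-%02d_run-%d_trace.tsv", i, nRuns)))
    }
  }
  subjects <- do.call(rbind, subj)

  # state-mindfulness change generated from the measured mediator chain
  smsChange <- withSeed(subSeed(seed, 9999L), {
    stdConn <- as.numeric(scale(subjects$conn_change))
    8 * (-0.76 * stdConn + 0.18 * as.numeric(scale(subjects$tit_last)) +
           0.6 * stats::rnorm(nSubjects)) + 5
  })
  subjects$sms_change <- smsChange

  targetTest <- groupTargetTest(subjects$tit_mean)
  prepost <- prepostChange(preMapsAll, postMapsAll, regionMask,
                           covariate = subjects$fd_post - subjects$fd_pre,
                           q = cfgGet(config, "fdrQ"), affine = affine)
  corPerfConn <- pearsonTest(subjects$tit_last, subjects$conn_change)
  corConnSms <- pearsonTest(subjects$conn_change, subjects$sms_change)
  med <- mediate(subjects$tit_last, subjects$conn_change,
                 subjects$sms_change)
  icc <- iccAbsoluteAgreement(subjects$wnc_session1, subjects$wnc_session2)

  out <- list(subjects = subjects, targetTest = targetTest,
              prepost = prepost, corPerfConn = corPerfConn,
              corConnSms = corConnSms, mediation = med, icc = icc,
              config = config, seed = seed)
  if (!is.null(outdir)) {
    writeCohortCSV(data.frame(nf_performance = subjects$tit_last,
                              conn_change = subjects$conn_change,
                              sms_change = subjects$sms_change),
                   file.path(outdir, "cohort.csv"))
    summaryJSON <- list(
      seed = seed,
      config = config@values,
      subjects = subjects,
      mean_conn_change = mean(subjects$conn_change),
      time_in_target_mean = mean(subjects$tit_mean),
      target_test_p = unname(targetTest$p.value),
      n_fdr_clusters = nrow(prepost$clusters),
      mediation = med@paths,
      sobel_z = med@sobelZ, sobel_p = med@sobelP,
      icc = icc$icc)
    jsonlite::write_json(summaryJSON,
                         file.path(outdir, "session_summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
  }
  out
}
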