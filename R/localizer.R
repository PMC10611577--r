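#' Decompose a run into spatial components
#'
#' Applies a spatial source-separation decomposition (PCA whitening followed
#' by symmetric FastICA) to the in-brain voxel x time matrix of a
#' (concatenated) run, after removing a per-voxel linear trend. The contract
#' of this stage is recoverability, not algorithmic novelty: networks planted
#' by the synthetic generator come back as components with high absolute
#' spatial correlation.
#'
#' @param series a \linkS4class{VolumeSeries} (concatenated runs).
#' @param nComponents number of components to extract (default 30, the
#'   conventional resting-state dimensionality); must not exceed the number
#'   of volumes.
#' @param brainMask logical 3-D array of in-brain voxels; default: voxels
#'   with non-zero temporal variance.
#' @param seed integer seed (random orthogonal initialisation); the same
#'   input and seed give identical components.
#' @return A \linkS4class{ComponentSet}. Component loadings outside the brain
#'   mask are zero.
#' @export
decomposeComponents <- function(series, nComponents = 30, brainMask = NULL,
                                seed = 1) {
  stopifnot(is(series, "VolumeSeries"))
  d <- dim(volData(series))
  tlen <- d[4L]
  stopIf(nComponents > tlen,
         "nComponents must not exceed the number of volumes")
  Y <- matrix(volData(series), prod(d[1:3]), tlen)   # V x T
  if (is.null(brainMask)) {
    v <- matrixStatsRowVar(Y)
    brainMask <- array(v > 1e-12, d[1:3])
  }
  idx <- maskIndices(brainMask)
  stopIf(length(idx) < nComponents, "brain mask smaller than nComponents")
  X <- t(detrendColumns(t(Y[idx, , drop = FALSE])))  # detrend over time
  dec <- spatialICA(X, nComponents, seed = seed)
  maps <- array(0, c(d[1:3], nComponents))
  flat <- matrix(0, prod(d[1:3]), nComponents)
  flat[idx, ] <- dec$S
  maps[] <- flat
  new("ComponentSet", maps = maps, timecourses = dec$A,
      brainMask = array(as.logical(brainMask), d[1:3]))
}

# row variances without matrixStats dependency
matrixStatsRowVar <- function(Y) {
  mu <- rowMeans(Y)
  rowSums((Y - mu)^2) / (ncol(Y) - 1L)
}

#' Spatial correlation between two maps
#'
#' Pearson correlation of two 3-D fields over the in-mask voxels (the
#' statistic fslcc reports). Symmetric in its arguments.
#'
#' @param mapA,mapB 3-D arrays of identical shape.
#' @param brainMask logical 3-D array (>= 2 voxels); default all voxels.
#' @return correlation coefficient.
#' @export
spatialCorrelation <- function(mapA, mapB, brainMask = NULL) {
  stopIf(!identical(dim(mapA), dim(mapB)), "map shapes differ")
  if (is.null(brainMask)) brainMask <- array(TRUE, dim(mapA))
  idx <- maskIndices(brainMask)
  stopIf(length(idx) < 2L, "mask must contain at least 2 voxels")
  a <- mapA[idx]; b <- mapB[idx]
  r <- safeCor(a, b)
  stopIf(is.na(r), "zero-variance map within mask: correlation undefined")
  r
}

#' Match components to template network maps
#'
#' For each template, selects the component with the highest absolute spatial
#' correlation; the component's loadings are sign-flipped when the best match
#' is negative (source separation has a sign ambiguity). If one component
#' wins two templates it is assigned to the template with the larger |r| and
#' the runner-up component serves the other, so that the selected networks
#' are always distinct.
#'
#' @param components a \linkS4class{ComponentSet} (>= 2 components).
#' @param templates named list of 3-D template fields (e.g. DMN, CEN).
#' @param brainMask logical 3-D array; default: the component set's mask.
#' @return named list (one element per template) with fields
#'   \code{component} (index), \code{r} (signed match correlation),
#'   \code{map} (sign-aligned loading field).
#' @export
selectComponents <- function(components, templates, brainMask = NULL) {
  stopifnot(is(components, "ComponentSet"))
  k <- nComponents(components)
  stopIf(k < 2L, "need at least 2 components")
  if (is.null(brainMask)) brainMask <- components@brainMask
  R <- sapply(templates, function(tpl) {
    sapply(seq_len(k), function(i) {
      r <- tryCatch(spatialCorrelation(componentMap(components, i), tpl,
                                       brainMask),
                    error = function(e) NA_real_)
      r
    })
  })                                       # k x nTemplates signed r
  stopIf(all(is.na(R)), "all components degenerate: selection impossible")
  absR <- abs(R); absR[is.na(absR)] <- -Inf
  picks <- apply(absR, 2, which.max)
  # resolve collisions: stronger |r| keeps the component, loser takes runner-up
  if (anyDuplicated(picks)) {
    ord <- order(absR[cbind(picks, seq_along(picks))], decreasing = TRUE)
    taken <- integer(0)
    for (j in ord) {
      cand <- order(absR[, j], decreasing = TRUE)
      cand <- cand[!(cand %in% taken)]
      picks[j] <- cand[1L]
      taken <- c(taken, cand[1L])
    }
  }
  out <- lapply(seq_along(templates), function(j) {
    i <- as.integer(unname(picks[j]))
    r <- unname(R[i, j])
    m <- componentMap(components, i)
    if (!is.na(r) && r < 0) m <- -m
    list(component = i, r = r, map = m)
  })
  names(out) <- names(templates)
  out
}

#' Threshold a loading map at its upper fraction and binarize
#'
#' Keeps exactly \code{ceiling(topFraction * n_inbrain)} voxels with the
#' highest loadings (the conventional "upper 10\%" rule), breaking ties by
#' lexicographic voxel index so the result is deterministic.
#'
#' @param map 3-D loading field.
#' @param brainMask logical 3-D array of in-brain voxels; the fraction is
#'   taken relative to in-brain voxels, not the whole grid.
#' @param topFraction proportion of in-brain voxels to keep (0 < f < 1;
#'   default 0.10).
#' @param label network label to attach.
#' @param sourceComponent,matchR provenance to attach.
#' @return A \linkS4class{NetworkMask} with exactly the prescribed number of
#'   selected voxels.
#' @export
thresholdAndBinarize <- function(map, brainMask = NULL, topFraction = 0.10,
                                 label = "NOI",
                                 sourceComponent = NA_integer_,
                                 matchR = NA_real_) {
  stopIf(topFraction <= 0 || topFraction >= 1,
         "topFraction must be in (0, 1)")
  if (is.null(brainMask)) brainMask <- array(TRUE, dim(map))
  idx <- maskIndices(brainMask)
  stopIf(length(idx) == 0L, "empty brain mask")
  nKeep <- as.integer(ceiling(topFraction * length(idx)))
  vals <- map[idx]
  keep <- idx[order(-vals, idx)[seq_len(nKeep)]]
  m <- array(FALSE, dim(map))
  m[keep] <- TRUE
  NetworkMask(m, label, sourceComponent = sourceComponent, matchR = matchR)
}

#' Compare mask sizes across subjects
#'
#' Paired t-test on the per-subject voxel counts of two sets of network masks
#' (e.g. DMN vs CEN), mirroring the standard sanity check that the two
#' personalized masks do not systematically differ in size.
#'
#' @param countsA,countsB integer vectors of per-subject voxel counts
#'   (or lists of \linkS4class{NetworkMask} objects).
#' @param alternative test sidedness (default two-sided).
#' @return the \code{\link{pairedT}} report.
#' @export
compareMaskSizes <- function(countsA, countsB, alternative = "two.sided") {
  if (is.list(countsA)) countsA <- vapply(countsA, voxelCount, numeric(1))
  if (is.list(countsB)) countsB <- vapply(countsB, voxelCount, numeric(1))
  stopIf(length(countsA) != length(countsB), "count vectors differ in length")
  stopIf(length(countsA) < 2L, "need at least 2 subjects")
  pairedT(countsA, countsB, alternative = alternative)
}

#' Personalized network localization, end to end
#'
#' Convenience wrapper chaining \code{decomposeComponents},
#' \code{selectComponents} and \code{thresholdAndBinarize}: decompose a
#' localizer run, match components to the supplied templates, and return one
#' binarized \linkS4class{NetworkMask} per template.
#'
#' @param series concatenated localizer \linkS4class{VolumeSeries}.
#' @param templates named list of template fields (e.g. list(DMN=, CEN=)).
#' @param nComponents decomposition dimensionality.
#' @param topFraction binarization fraction (default 0.10).
#' @param brainMask optional logical 3-D array.
#' @param seed integer seed.
#' @return named list of \linkS4class{NetworkMask} objects.
#' @export
localizeNetworks <- function(series, templates, nComponents = 30,
                             topFraction = 0.10, brainMask = NULL, seed = 1) {
  comps <- decomposeComponents(series, nComponents = nComponents,
                               brainMask = brainMask, seed = seed)
  sel <- selectComponents(comps, templates, brainMask = brainMask)
  mask <- if (is.null(brainMask)) comps@brainMask else brainMask
  out <- lapply(names(sel), function(nm) {
    thresholdAndBinarize(sel[[nm]]$map, brainMask = mask,
                         topFraction = topFraction, label = nm,
                         sourceComponent = sel[[nm]]$component,
                         matchR = sel[[nm]]$r)
  })
  names(out) <- names(sel)
  out
}
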