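# Format readers/writers: NIfTI-1 volumes and masks, TSV confound and trace
# tables, CSV behavioral tables, JSON sidecars.

#' Write a VolumeSeries to NIfTI-1
#'
#' @param series a \linkS4class{VolumeSeries}.
#' @param path destination (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
writeVolumeSeries <- function(series, path) {
  stopifnot(is(series, "VolumeSeries"))
  img <- RNifti::asNifti(volData(series))
  aff <- voxelAffine(series)
  RNifti::pixdim(img) <- c(abs(diag(aff)[1:3]), repetitionTime(series))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a VolumeSeries from NIfTI-1
#'
#' @param path NIfTI file.
#' @param tr repetition time override; default: the file's 4th pixdim.
#' @return A \linkS4class{VolumeSeries}.
#' @export
readVolumeSeries <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  stopIf(length(d) != 4L, "expected a 4-D NIfTI volume")
  pd <- RNifti::pixdim(img)
  if (is.null(tr)) tr <- if (length(pd) >= 4L && pd[4L] > 0) pd[4L] else 1
  aff <- diag(c(pd[1:3], 1))
  VolumeSeries(array(as.numeric(img), d), tr = tr, affine = aff)
}

#' Write a binary mask to NIfTI-1
#'
#' @param mask a \linkS4class{NetworkMask} or logical 3-D array.
#' @param path destination.
#' @param voxelSize voxel size for the header (mm).
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path, voxelSize = c(2, 2, 2)) {
  m <- if (is(mask, "NetworkMask")) maskArray(mask) else mask
  img <- RNifti::asNifti(array(as.integer(m), dim(m)))
  RNifti::pixdim(img) <- voxelSize
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI-1
#'
#' @param path NIfTI file.
#' @param label network label to attach.
#' @return A \linkS4class{NetworkMask}.
#' @export
readMask <- function(path, label = "NOI") {
  img <- RNifti::readNifti(path)
  NetworkMask(array(as.numeric(img) != 0, dim(img)), label)
}

#' Write a confound table as TSV
#'
#' Columns: trans_x/y/z (mm), rot_x/y/z (radians), framewise_displacement,
#' global_signal_z, outlier (0/1), then any aCompCor columns
#' (w_comp_cor_k, c_comp_cor_k).
#'
#' @param confounds a \linkS4class{ConfoundSet}.
#' @param path destination TSV.
#' @return \code{path}, invisibly.
#' @export
writeConfoundsTSV <- function(confounds, path) {
  stopifnot(is(confounds, "ConfoundSet"))
  df <- as.data.frame(confounds@motion)
  names(df) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  df$framewise_displacement <- confounds@fd
  df$global_signal_z <- confounds@globalSignalZ
  df$outlier <- as.integer(confounds@outliers)
  if (ncol(confounds@compcorWM)) {
    wm <- as.data.frame(confounds@compcorWM)
    names(wm) <- paste0("w_comp_cor_", seq_len(ncol(wm)))
    df <- cbind(df, wm)
  }
  if (ncol(confounds@compcorCSF)) {
    cs <- as.data.frame(confounds@compcorCSF)
    names(cs) <- paste0("c_comp_cor_", seq_len(ncol(cs)))
    df <- cbind(df, cs)
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a confound table from TSV
#'
#' @param path TSV written by \code{\link{writeConfoundsTSV}} (or any table
#'   with the trans_x..rot_z dialect).
#' @return A \linkS4class{ConfoundSet}.
#' @export
readConfoundsTSV <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  stopIf(!all(need %in% names(df)),
         "confound TSV must contain trans_x..rot_z columns")
  motion <- as.matrix(df[, need])
  wm <- as.matrix(df[, grep("^w_comp_cor_", names(df)), drop = FALSE])
  cs <- as.matrix(df[, grep("^c_comp_cor_", names(df)), drop = FALSE])
  ConfoundSet(motion,
              fd = if ("framewise_displacement" %in% names(df))
                df$framewise_displacement else NULL,
              globalSignalZ = if ("global_signal_z" %in% names(df))
                df$global_signal_z else NULL,
              outliers = if ("outlier" %in% names(df))
                df$outlier != 0 else NULL,
              compcorWM = wm, compcorCSF = cs)
}

#' Write a per-run feedback trace as TSV
#'
#' One row per TR with the activation estimates, PDA, dot position and
#' baseline flag.
#'
#' @param run a \linkS4class{RunResult}.
#' @param path destination TSV.
#' @return \code{path}, invisibly.
#' @export
writeRunTrace <- function(run, path) {
  stopifnot(is(run, "RunResult"))
  df <- data.frame(tr = seq_along(run@pda), dmn = run@dmn, cen = run@cen,
                   pda = run@pda, dot_y = run@dotY,
                   baseline = as.integer(run@baseline))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a behavioral cohort as CSV
#'
#' @param cohort a \linkS4class{BehaviorCohort} or data.frame.
#' @param path destination CSV.
#' @return \code{path}, invisibly.
#' @export
writeCohortCSV <- function(cohort, path) {
  df <- if (is(cohort, "BehaviorCohort")) cohortData(cohort) else cohort
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a behavioral cohort from CSV
#'
#' @param path CSV with columns nf_performance, conn_change, sms_change.
#' @return data.frame.
#' @export
readCohortCSV <- function(path) {
  utils::read.csv(path)
}
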