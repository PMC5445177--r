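# NIfTI / CSV / JSON input-output.

#' Read a subject's MWF volume and masks from NIfTI files
#'
#' @param mwfPath path to the MWF map (values in \eqn{[0,1]}).
#' @param wmPath path to the binary white-matter mask on the same grid.
#' @param lesionPath optional path to a binary lesion mask; when given,
#'   the NAWM label is filled in as its WM complement.
#' @return A [LabeledVolume-class].
#' @seealso [writeLabeledVolume()]
#' @export
readMWFSubject <- function(mwfPath, wmPath, lesionPath = NULL) {
  values <- asPlainArray(RNifti::readNifti(mwfPath))
  img <- RNifti::readNifti(wmPath)
  wm <- asPlainArray(img) > 0.5
  lesion <- NULL
  nawm <- NULL
  if (!is.null(lesionPath)) {
    lesion <- asPlainArray(RNifti::readNifti(lesionPath)) > 0.5
    nawm <- wm & !lesion
  }
  labeledVolume(values, wm, lesion = lesion, nawm = nawm,
                affine = unclass(RNifti::xform(img)))
}

# RNifti images are arrays with extra attributes; strip to a plain array.
asPlainArray <- function(img) {
  array(as.numeric(img), dim = dim(img))
}

#' Write a labeled volume as a set of NIfTI files
#'
#' Writes the scalar map plus whichever label volumes are present
#' (`wm`, `lesion`, `nawm`, `dirty`) with a shared affine.
#'
#' @param volume a [LabeledVolume-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the paths written.
#' @export
writeLabeledVolume <- function(volume, dir, prefix = "subject") {
  stopifnot(is(volume, "LabeledVolume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  writeOne <- function(arr, what) {
    path <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, what))
    img <- RNifti::asNifti(arr)
    RNifti::writeNifti(img, path)
    path
  }
  paths <- c(paths, writeOne(volume@values, "values"))
  paths <- c(paths, writeOne(volume@wm * 1L, "wm"))
  for (nm in c("lesion", "nawm", "dirty")) {
    g <- slot(volume, nm)
    if (!is.null(g)) paths <- c(paths, writeOne(g * 1L, nm))
  }
  invisible(paths)
}

#' Read or write a cohort feature table
#'
#' The CSV schema is the one produced by [makeCohort()] and
#' [runStudy()]: one row per subject with columns `subject_id`, `group`,
#' `m1`, `m2`, `lambda`, `mean_lesion_mwf`, `mean_nawm_mwf`, `age`,
#' `gender`, `dd`, `dmt`, `cortical_thickness`.
#'
#' @param path CSV path.
#' @param table data frame to write.
#' @return `readCohort`: the data frame.
#' @export
readCohort <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname readCohort
#' @export
writeCohort <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

# Plain-list views of S4 results, for JSON serialization.
fitToList <- function(fit) {
  if (is(fit, "SingleGammaFit")) {
    list(type = "single",
         shape = fit@component@shape, scale = fit@component@scale,
         mode = componentMode(fit@component),
         logLik = fit@logLik, nObs = fit@nObs, nDropped = fit@nDropped,
         converged = fit@converged)
  } else {
    m <- fit@model
    list(type = "mixture", lambda = m@lambda,
         shape1 = m@comp1@shape, scale1 = m@comp1@scale,
         m1 = componentMode(m@comp1),
         shape2 = m@comp2@shape, scale2 = m@comp2@scale,
         m2 = componentMode(m@comp2),
         logLik = fit@logLik, nIter = fit@nIter,
         converged = fit@converged, nObs = fit@nObs,
         nDropped = fit@nDropped)
  }
}

selectionToList <- function(sel) {
  list(statistic = sel@statistic, pValue = sel@pValue,
       chosen = sel@chosen, nBootstrap = sel@nBootstrap,
       alpha = sel@alpha)
}

regressionToList <- function(fit) {
  list(predictors = as.list(fit@predictors),
       coefficients = as.list(fit@coefficients),
       se = as.list(fit@se), pValues = as.list(fit@pValues),
       r2 = fit@r2, adjR2 = fit@adjR2, cvMSE = fit@cvMSE, n = fit@n,
       response = fit@response)
}

writeJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
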