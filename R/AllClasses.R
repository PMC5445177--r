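#' @useDynLib mwfmix, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats dgamma pgamma qgamma rgamma rnorm runif quantile median
#'   var sd optimize optim integrate lm lm.fit t.test coef plogis qlogis
#'   setNames model.matrix pt rbinom
#' @importFrom utils head read.csv write.csv
NULL

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' One gamma component of the MWF mixture
#'
#' Holds the shape \eqn{\alpha} and scale \eqn{\beta} of a single gamma
#' distribution. In the whole-brain white-matter MWF model each subject's
#' MWF histogram is described by two such components, one for low-MWF
#' (lesional and dirty) white matter and one for high-MWF normal-appearing
#' white matter. The distribution mode, \eqn{\max(0, (\alpha-1)\beta)}, is
#' the summary carried into group analyses.
#'
#' @slot shape positive dimensionless shape \eqn{\alpha}.
#' @slot scale positive scale \eqn{\beta}, in MWF units.
#' @seealso [gammaComponent()], [componentMode()]
#' @export
setClass("GammaComponent",
         representation(shape = "numeric", scale = "numeric"))

setValidity("GammaComponent", function(object) {
  msg <- character()
  if (length(object@shape) != 1L || !is.finite(object@shape) ||
      object@shape <= 0)
    msg <- c(msg, "'shape' must be a single positive finite number")
  if (length(object@scale) != 1L || !is.finite(object@scale) ||
      object@scale <= 0)
    msg <- c(msg, "'scale' must be a single positive finite number")
  if (length(msg)) msg else TRUE
})

#' Two-component gamma mixture model of white-matter MWF
#'
#' The subject-level statistical reduction: a mixture
#' \eqn{\lambda\,\Gamma(\alpha_1,\beta_1) + (1-\lambda)\,\Gamma(\alpha_2,\beta_2)}
#' where the first component has the lower mode (lesion-like, mode
#' \eqn{m_1}) and the second the higher mode (NAWM-like, mode \eqn{m_2}).
#' Components are stored in canonical order \eqn{m_1 \le m_2}; the mixing
#' ratio \eqn{\lambda} is the weight of the low-mode component.
#'
#' @slot lambda mixing ratio in \eqn{[0, 1]}, weight of the low-mode
#'   component.
#' @slot comp1 [GammaComponent-class] with the lower mode.
#' @slot comp2 [GammaComponent-class] with the higher mode.
#' @seealso [gammaMixtureModel()], [referenceMixture()], [fitGammaMixture()]
#' @export
setClass("GammaMixtureModel",
         representation(lambda = "numeric",
                        comp1 = "GammaComponent",
                        comp2 = "GammaComponent"))

setValidity("GammaMixtureModel", function(object) {
  msg <- character()
  if (length(object@lambda) != 1L || !is.finite(object@lambda) ||
      object@lambda < 0 || object@lambda > 1)
    msg <- c(msg, "'lambda' must be a single number in [0, 1]")
  m1 <- max(0, (object@comp1@shape - 1) * object@comp1@scale)
  m2 <- max(0, (object@comp2@shape - 1) * object@comp2@scale)
  if (m1 > m2)
    msg <- c(msg, "components must be ordered: mode(comp1) <= mode(comp2)")
  if (length(msg)) msg else TRUE
})

#' Fit results for subject-level MWF distribution models
#'
#' `GammaFit` is the virtual parent of the two concrete fit classes.
#' `SingleGammaFit` holds the maximum-likelihood single-gamma fit;
#' `GammaMixtureFit` holds the EM (optionally quasi-Newton refined)
#' two-component mixture fit together with its per-iteration
#' log-likelihood trace.
#'
#' @slot logLik maximised observed-data log-likelihood, in nats.
#' @slot nIter number of iterations used.
#' @slot converged whether the stopping rule was met before `maxIter`.
#' @slot nObs number of (strictly positive) observations fitted.
#' @slot nDropped number of non-positive values excluded before fitting.
#' @aliases SingleGammaFit-class GammaMixtureFit-class
#' @seealso [fitSingleGamma()], [fitGammaMixture()], [summarizeFit()]
#' @export
setClass("GammaFit",
         representation("VIRTUAL",
                        logLik = "numeric", nIter = "integer",
                        converged = "logical", nObs = "integer",
                        nDropped = "integer"))

#' @rdname GammaFit-class
#' @slot component the fitted [GammaComponent-class].
#' @export
setClass("SingleGammaFit", contains = "GammaFit",
         representation(component = "GammaComponent"))

#' @rdname GammaFit-class
#' @slot model the fitted [GammaMixtureModel-class] in canonical order.
#' @slot trace observed-data log-likelihood after each EM iteration.
#' @export
setClass("GammaMixtureFit", contains = "GammaFit",
         representation(model = "GammaMixtureModel", trace = "numeric"))

#' Outcome of the penalized likelihood ratio model choice
#'
#' Stores the penalized likelihood ratio statistic comparing the
#' two-component gamma mixture against the single gamma, the parametric
#' bootstrap p-value, and which model was chosen at the given level.
#'
#' @slot statistic penalized LRT statistic on the \eqn{2\times} scale, nats.
#' @slot pValue bootstrap exceedance p-value.
#' @slot chosen `"single"` or `"mixture"`.
#' @slot nBootstrap number of parametric bootstrap replicates.
#' @slot alpha significance level used for the choice.
#' @slot bootStats the replicate statistics (diagnostic).
#' @seealso [penalizedLRT()]
#' @export
setClass("MixtureSelection",
         representation(statistic = "numeric", pValue = "numeric",
                        chosen = "character", nBootstrap = "integer",
                        alpha = "numeric", bootStats = "numeric"))

setValidity("MixtureSelection", function(object) {
  msg <- character()
  if (!object@chosen %in% c("single", "mixture"))
    msg <- c(msg, "'chosen' must be \"single\" or \"mixture\"")
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "'pValue' must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' A scalar volume with white-matter / lesion / NAWM labels
#'
#' Container for one subject's 3D scalar map (MWF values in \eqn{[0,1]},
#' or an arbitrary FLAIR-like intensity) together with binary label
#' volumes on the same voxel grid: the white-matter mask, and optionally
#' mutually exclusive lesion and NAWM masks partitioning it. A `dirty`
#' label marks the dirty-WM rim of synthetic volumes (a subset of NAWM).
#'
#' @slot values 3D numeric array.
#' @slot wm 3D logical array, the white-matter mask.
#' @slot lesion optional 3D logical array, subset of `wm`.
#' @slot nawm optional 3D logical array, `wm` minus `lesion`.
#' @slot dirty optional 3D logical array, dirty-WM rim (subset of `nawm`).
#' @slot affine 4x4 voxel-to-world matrix carried through NIfTI IO.
#' @seealso [labeledVolume()], [makeMWFVolume()], [wmValues()]
#' @export
setClass("LabeledVolume",
         representation(values = "array", wm = "array",
                        lesion = "arrayOrNULL", nawm = "arrayOrNULL",
                        dirty = "arrayOrNULL", affine = "matrix"))

setValidity("LabeledVolume", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L)
    msg <- c(msg, "'values' must be a 3D array")
  if (!identical(dim(object@wm), d))
    msg <- c(msg, "'wm' must share the grid of 'values'")
  if (!is.logical(object@wm))
    msg <- c(msg, "'wm' must be logical")
  for (nm in c("lesion", "nawm", "dirty")) {
    g <- slot(object, nm)
    if (!is.null(g)) {
      if (!identical(dim(g), d) || !is.logical(g))
        msg <- c(msg, sprintf("'%s' must be a logical array on the same grid",
                              nm))
      else if (any(g & !object@wm))
        msg <- c(msg, sprintf("'%s' must be a subset of the WM mask", nm))
    }
  }
  if (!is.null(object@lesion) && !is.null(object@nawm)) {
    if (any(object@lesion & object@nawm))
      msg <- c(msg, "lesion and NAWM masks must be disjoint")
    if (!all(object@wm == (object@lesion | object@nawm)))
      msg <- c(msg, "lesion and NAWM masks must partition the WM mask")
  }
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "'affine' must be a 4x4 matrix")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic MWF volume
#'
#' Ground-truth description used by [makeMWFVolume()]: an ellipsoidal
#' white-matter mask on a voxel grid, spherical lesions with a dirty-WM
#' rim, and the two-component gamma mixture the pooled WM values should
#' follow.
#'
#' @slot gridShape integer length-3 voxel counts.
#' @slot wmFraction target fraction of the grid inside the WM mask.
#' @slot nLesions lesion count; `NA` means "fill until the low-MWF voxel
#'   fraction matches the mixture's lambda".
#' @slot lesionRadiusRange radii range, voxels.
#' @slot dirtyRimWidth rim width, voxels.
#' @slot mixture ground-truth [GammaMixtureModel-class].
#' @slot dirtyOverlap fraction in \eqn{[0,1]} of dirty-rim voxels that
#'   carry the low component's largest realized draws.
#' @slot seed integer RNG seed.
#' @seealso [volumeSpec()]
#' @export
setClass("VolumeSpec",
         representation(gridShape = "integer", wmFraction = "numeric",
                        nLesions = "integer", lesionRadiusRange = "numeric",
                        dirtyRimWidth = "numeric",
                        mixture = "GammaMixtureModel",
                        dirtyOverlap = "numeric", seed = "integer"))

setValidity("VolumeSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
    msg <- c(msg, "'gridShape' must be three voxel counts >= 8")
  if (object@wmFraction <= 0 || object@wmFraction > 0.52)
    msg <- c(msg, "'wmFraction' must be in (0, 0.52] for an inscribed ellipsoid")
  if (!is.na(object@nLesions) && object@nLesions < 0L)
    msg <- c(msg, "'nLesions' must be >= 0")
  if (length(object@lesionRadiusRange) != 2L ||
      any(object@lesionRadiusRange < 1) ||
      diff(object@lesionRadiusRange) < 0)
    msg <- c(msg, "'lesionRadiusRange' must be an increasing pair of radii >= 1")
  if (object@dirtyOverlap < 0 || object@dirtyOverlap > 1)
    msg <- c(msg, "'dirtyOverlap' must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic patient cohort
#'
#' Describes how per-subject predictors are sampled and how cortical
#' thickness is generated from them through a linear model with Gaussian
#' noise, for [makeCohort()].
#'
#' @slot nSubjects number of subjects.
#' @slot groupLabel `"RRMS"` or `"SPMS"`.
#' @slot trueCoefficients named numeric: `"(Intercept)"` plus
#'   thickness-units-per-predictor-unit coefficients.
#' @slot noiseSD residual SD of cortical thickness, mm.
#' @slot predictorDistributions named list of sampling rules (see
#'   [cohortSpec()]).
#' @slot seed integer RNG seed.
#' @seealso [cohortSpec()], [rrmsCohortSpec()], [spmsCohortSpec()]
#' @export
setClass("CohortSpec",
         representation(nSubjects = "integer", groupLabel = "character",
                        trueCoefficients = "numeric", noiseSD = "numeric",
                        predictorDistributions = "list", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  npred <- sum(names(object@trueCoefficients) != "(Intercept)")
  if (object@nSubjects < max(2L, 1L + npred))
    msg <- c(msg, "'nSubjects' must be at least max(2, 1 + number of predictors)")
  if (object@noiseSD < 0)
    msg <- c(msg, "'noiseSD' must be >= 0")
  if (!"(Intercept)" %in% names(object@trueCoefficients))
    msg <- c(msg, "'trueCoefficients' must include \"(Intercept)\"")
  if (length(msg)) msg else TRUE
})

#' A fitted linear model on a predictor subset
#'
#' Ordinary least-squares fit of cortical thickness (or another response)
#' on a subset of subject-level features, with the goodness-of-fit and
#' cross-validation summaries used by the exhaustive model search.
#'
#' @slot predictors character vector of predictor names (without intercept).
#' @slot coefficients named numeric, intercept first.
#' @slot se coefficient standard errors.
#' @slot pValues two-sided coefficient p-values.
#' @slot r2 coefficient of determination.
#' @slot adjR2 adjusted R-squared, \eqn{1-(1-R^2)(n-1)/(n-p-1)}.
#' @slot cvMSE k-fold cross-validation mean squared error (mm^2); `NA`
#'   when the model was fitted without cross-validation.
#' @slot n number of subjects.
#' @slot response response column name.
#' @seealso [fitOLS()], [exhaustiveCVSelect()]
#' @export
setClass("RegressionFit",
         representation(predictors = "character", coefficients = "numeric",
                        se = "numeric", pValues = "numeric",
                        r2 = "numeric", adjR2 = "numeric", cvMSE = "numeric",
                        n = "integer", response = "character"))

#' Group-level comparison of Dice overlaps
#'
#' Per-subject Dice coefficients of a reference mask (lesion or NAWM)
#' against the two mode-derived ROIs, with the Welch two-sample t-test of
#' the difference.
#'
#' @slot diceM1 per-subject Dice of the reference mask with ROI[m1].
#' @slot diceM2 per-subject Dice of the reference mask with ROI[m2].
#' @slot reference `"lesion"` or `"nawm"`.
#' @slot tStat Welch t statistic.
#' @slot df Welch--Satterthwaite degrees of freedom.
#' @slot pValue two-sided p-value.
#' @slot direction which ROI has the larger mean Dice.
#' @slot nExcluded subjects dropped because a Dice value was undefined.
#' @seealso [compareDiceGroups()]
#' @export
setClass("DiceComparison",
         representation(diceM1 = "numeric", diceM2 = "numeric",
                        reference = "character", tStat = "numeric",
                        df = "numeric", pValue = "numeric",
                        direction = "character", nExcluded = "integer"))
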