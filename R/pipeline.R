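# End-to-end orchestration: per-subject reduction and the full
# desk-scale study.

#' Reduce one subject's MWF volume
#'
#' Runs the subject-level analysis: fits the single gamma and the
#' two-component mixture to the pooled WM MWF values, chooses between
#' them with the penalized likelihood ratio test, and derives
#' \eqn{(m_1, m_2, \lambda)}. When a lesion label is present, also
#' computes the NAWM mask, the mean MWF inside lesion and NAWM, the
#' mode-derived ROIs and their Dice overlap with both masks.
#'
#' If the selection prefers the single gamma, the mixture-derived
#' feature fields are `NA` and `features$mixture_preferred` is `FALSE`;
#' such subjects are retained in cohort tables but excluded from
#' mixture-parameter analyses.
#'
#' @param volume a [LabeledVolume-class] (lesion label optional).
#' @param nBootstrap bootstrap replicates for the model choice.
#' @param alpha significance level of the model choice.
#' @param seed integer seed (bootstrap).
#' @param subjectId identifier recorded in the feature row.
#' @return A list with `features` (one-row data frame), `singleFit`,
#'   `mixtureFit`, `selection`, and -- when a lesion label is present --
#'   `rois` and `dice`.
#' @examples
#' vol <- makeMWFVolume(volumeSpec(gridShape = c(32, 32, 16), seed = 3))
#' sub <- runSubject(vol, nBootstrap = 19, seed = 3)
#' sub$features
#' @export
runSubject <- function(volume, nBootstrap = 199L, alpha = 0.05,
                       seed = 1L, subjectId = "subject") {
  stopifnot(is(volume, "LabeledVolume"))
  x <- wmValues(volume)
  single <- fitSingleGamma(x)
  mixture <- tryCatch(fitGammaMixture(x), error = function(e) NULL)
  if (is.null(mixture)) {
    # component collapse: the data carry no mixture support
    selection <- new("MixtureSelection", statistic = -Inf, pValue = 1,
                     chosen = "single", nBootstrap = 0L, alpha = alpha,
                     bootStats = numeric(0))
  } else {
    selection <- penalizedLRT(single, mixture, x, nBootstrap = nBootstrap,
                              alpha = alpha, seed = seed)
  }
  mixturePreferred <- selection@chosen == "mixture"
  summary <- if (is.null(mixture)) c(m1 = NA_real_, m2 = NA_real_,
                                     lambda = NA_real_)
  else suppressWarnings(summarizeFit(mixture))
  features <- data.frame(
    subject_id = subjectId,
    m1 = if (mixturePreferred) summary[["m1"]] else NA_real_,
    m2 = if (mixturePreferred) summary[["m2"]] else NA_real_,
    lambda = if (mixturePreferred) summary[["lambda"]] else NA_real_,
    mean_lesion_mwf = NA_real_,
    mean_nawm_mwf = NA_real_,
    mixture_preferred = mixturePreferred,
    stringsAsFactors = FALSE)
  out <- list(features = features, singleFit = single,
              mixtureFit = mixture, selection = selection)
  if (!is.null(volume@lesion)) {
    nawm <- nawmMask(volume)
    if (any(volume@lesion))
      features$mean_lesion_mwf <- mean(volume@values[volume@lesion])
    features$mean_nawm_mwf <- mean(volume@values[nawm])
  }
  if (!is.null(volume@lesion) && !is.na(summary[["m1"]])) {
    nawm <- nawmMask(volume)
    rois <- roiFromModes(volume, summary[["m1"]], summary[["m2"]])
    dice <- list(
      lesion_roiM1 = tryCatch(diceCoefficient(volume@lesion, rois$roiM1),
                              error = function(e) NA_real_),
      lesion_roiM2 = tryCatch(diceCoefficient(volume@lesion, rois$roiM2),
                              error = function(e) NA_real_),
      nawm_roiM1 = tryCatch(diceCoefficient(nawm, rois$roiM1),
                            error = function(e) NA_real_),
      nawm_roiM2 = tryCatch(diceCoefficient(nawm, rois$roiM2),
                            error = function(e) NA_real_))
    out$rois <- rois
    out$dice <- dice
    out$features <- features
  }
  out$features <- features
  out
}

#' Configuration for a desk-scale simulated study
#'
#' @param nPerGroup named integer vector: subjects per group.
#' @param gridShape voxel grid of each simulated subject.
#' @param nBootstrap bootstrap replicates per subject for model choice.
#' @param cvFolds folds of the model-search cross-validation.
#' @param seed master seed; all per-subject seeds derive from it.
#' @param nLesions lesion count per subject (`NA`: match each subject's
#'   mixing ratio).
#' @param lesionRadiusRange lesion radius range in voxels (scale it down
#'   with the grid).
#' @param outDir optional output directory for the results bundle.
#' @return A list understood by [runStudy()].
#' @export
studyConfig <- function(nPerGroup = c(RRMS = 10L, SPMS = 10L),
                        gridShape = c(64L, 64L, 32L),
                        nBootstrap = 99L, cvFolds = 10L, seed = 1L,
                        nLesions = NA_integer_,
                        lesionRadiusRange = c(3, 6), outDir = NULL) {
  list(nPerGroup = nPerGroup, gridShape = gridShape,
       nBootstrap = nBootstrap, cvFolds = cvFolds,
       seed = as.integer(seed), nLesions = as.integer(nLesions),
       lesionRadiusRange = lesionRadiusRange, outDir = outDir)
}

# Per-group generative settings: subject-level mixture parameters are
# drawn from the same distributions the cohort generator uses, and
# thickness follows the group's true coefficient model applied to the
# subject's true (generative) parameters.
studyGroupSpec <- function(group, n, seed) {
  if (group == "RRMS") rrmsCohortSpec(n, seed = seed)
  else spmsCohortSpec(n, seed = seed)
}

#' Run the full desk-scale study on simulated subjects
#'
#' Simulates each subject's MWF volume from per-subject ground-truth
#' mixture parameters (drawn from the group's distributions), fits the
#' reduction per subject, compares Dice overlaps per group, assembles
#' the cohort feature table (cortical thickness generated from the
#' subjects' true parameters through the group's linear model), and runs
#' both predictor-set regressions with LMG importance for the selected
#' gamma-set model, plus Welch between-group comparisons.
#'
#' The bundle is deterministic under `config$seed`. If `outDir` is set,
#' results are written as CSV/JSON (cohort table, Dice tables, model
#' reports, manifest). Stage failures are recorded in the manifest
#' (`errors`) and leave a partial bundle rather than aborting.
#'
#' @param config a [studyConfig()] list.
#' @return A list: `cohort`, `subjects`, `dice` (per group, per
#'   reference mask), `models` (per group), `welch` (between-group
#'   tests), `manifest`.
#' @export
runStudy <- function(config = studyConfig()) {
  manifest <- list(seed = config$seed, nPerGroup = as.list(config$nPerGroup),
                   gridShape = config$gridShape,
                   nBootstrap = config$nBootstrap,
                   cvFolds = config$cvFolds,
                   package = as.character(utils::packageVersion("mwfmix")),
                   errors = list())
  subjects <- list()
  cohortRows <- list()
  subjectIdx <- 0L
  for (group in names(config$nPerGroup)) {
    n <- config$nPerGroup[[group]]
    gspec <- studyGroupSpec(group, max(n, 6L), seed = config$seed + 1000L)
    truth <- makeCohort(gspec)[seq_len(n), , drop = FALSE]
    for (i in seq_len(n)) {
      subjectIdx <- subjectIdx + 1L
      sid <- sprintf("%s%03d", group, i)
      mix <- gammaMixtureModel(
        truth$lambda[i],
        gammaComponent(2, truth$m1[i] / (2 - 1)),
        gammaComponent(5, truth$m2[i] / (5 - 1)))
      vspec <- volumeSpec(gridShape = config$gridShape, mixture = mix,
                          nLesions = config$nLesions,
                          lesionRadiusRange = config$lesionRadiusRange,
                          seed = config$seed + subjectIdx)
      vol <- makeMWFVolume(vspec)
      sub <- runSubject(vol, nBootstrap = config$nBootstrap,
                        seed = config$seed + subjectIdx, subjectId = sid)
      sub$volume <- vol
      sub$group <- group
      row <- sub$features
      row$group <- group
      # covariates and thickness from the generative cohort model
      for (nm in c("age", "gender", "dd", "dmt"))
        row[[nm]] <- truth[[nm]][i]
      row$true_m1 <- truth$m1[i]
      row$true_m2 <- truth$m2[i]
      row$true_lambda <- truth$lambda[i]
      row$cortical_thickness <- truth$cortical_thickness[i]
      cohortRows[[sid]] <- row
      subjects[[sid]] <- sub
    }
  }
  cohort <- do.call(rbind, cohortRows)
  rownames(cohort) <- NULL
  canonical <- c("subject_id", "group", "m1", "m2", "lambda",
                 "mean_lesion_mwf", "mean_nawm_mwf", "age", "gender",
                 "dd", "dmt", "cortical_thickness")
  cohort <- cohort[, c(canonical, setdiff(colnames(cohort), canonical))]
  out <- list(cohort = cohort, subjects = subjects, dice = list(),
              models = list(), welch = list(), manifest = manifest)

  # Dice comparisons per group
  for (group in names(config$nPerGroup)) {
    ids <- names(subjects)[vapply(subjects, function(s) s$group == group,
                                  logical(1))]
    triplesL <- lapply(ids, function(id) {
      s <- subjects[[id]]
      list(mask = s$volume@lesion, roiM1 = s$rois$roiM1,
           roiM2 = s$rois$roiM2)
    })
    triplesN <- lapply(ids, function(id) {
      s <- subjects[[id]]
      list(mask = nawmMask(s$volume), roiM1 = s$rois$roiM1,
           roiM2 = s$rois$roiM2)
    })
    res <- tryCatch(
      list(lesion = compareDiceGroups(triplesL, "lesion"),
           nawm = compareDiceGroups(triplesN, "nawm")),
      error = function(e) e)
    if (inherits(res, "error")) {
      out$manifest$errors[[paste0("dice_", group)]] <- conditionMessage(res)
    } else {
      out$dice[[group]] <- res
    }
  }

  # Group regressions on subjects whose selection kept the mixture
  for (group in names(config$nPerGroup)) {
    sub <- cohort[cohort$group == group & cohort$mixture_preferred, ,
                  drop = FALSE]
    res <- tryCatch({
      k <- min(config$cvFolds, nrow(sub))
      cmp <- comparePredictorSets(sub, k = k, seed = config$seed)
      lmg <- if (length(cmp$gamma$best@predictors) >= 1)
        lmgImportance(sub, cmp$gamma$best@predictors)
      else NULL
      list(comparison = cmp, lmg = lmg)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$manifest$errors[[paste0("models_", group)]] <- conditionMessage(res)
    } else {
      out$models[[group]] <- res
    }
  }

  # Between-group Welch comparisons
  groups <- names(config$nPerGroup)
  if (length(groups) == 2L) {
    a <- cohort[cohort$group == groups[1], ]
    b <- cohort[cohort$group == groups[2], ]
    for (v in c("m1", "m2", "lambda", "cortical_thickness")) {
      res <- tryCatch(welchT(a[[v]][!is.na(a[[v]])], b[[v]][!is.na(b[[v]])]),
                      error = function(e) e)
      if (!inherits(res, "error")) out$welch[[v]] <- res
    }
  }

  if (!is.null(config$outDir)) writeStudyBundle(out, config$outDir)
  out
}

# Serialize a study bundle to outDir as CSV/JSON.
writeStudyBundle <- function(study, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeCohort(study$cohort, file.path(outDir, "cohort.csv"))
  for (group in names(study$dice)) {
    d <- study$dice[[group]]
    tab <- data.frame(ref_mask = rep(c("lesion", "nawm"),
                                     times = c(length(d$lesion@diceM1),
                                               length(d$nawm@diceM1))),
                      dice_roi_m1 = c(d$lesion@diceM1, d$nawm@diceM1),
                      dice_roi_m2 = c(d$lesion@diceM2, d$nawm@diceM2))
    write.csv(tab, file.path(outDir, sprintf("dice_%s.csv", group)),
              row.names = FALSE)
  }
  models <- lapply(study$models, function(m) {
    list(gamma = regressionToList(m$comparison$gamma$best),
         mask = regressionToList(m$comparison$mask$best),
         better = m$comparison$better,
         lmg = if (!is.null(m$lmg)) as.list(m$lmg) else NULL)
  })
  writeJSON(models, file.path(outDir, "models.json"))
  writeJSON(study$welch, file.path(outDir, "welch.json"))
  fits <- lapply(study$subjects, function(s)
    list(fit = fitToList(s$mixtureFit),
         single = fitToList(s$singleFit),
         selection = selectionToList(s$selection),
         dice = s$dice))
  writeJSON(fits, file.path(outDir, "subjects.json"))
  writeJSON(study$manifest, file.path(outDir, "manifest.json"))
  invisible(outDir)
}

#' Plot a fitted mixture over the data histogram
#'
#' Presentation-only: the fit itself never uses a histogram or binning.
#'
#' @param values the MWF values that were fitted.
#' @param fit a [GammaMixtureFit-class] or [SingleGammaFit-class].
#' @param breaks histogram breaks (display only).
#' @return Invisibly, `NULL`.
#' @export
plotFit <- function(values, fit, breaks = 100) {
  cleaned <- dropNonPositive(values)
  x <- cleaned$values
  graphics::hist(x, breaks = breaks, freq = FALSE, col = "grey90",
                 border = "grey70", main = "WM MWF distribution",
                 xlab = "MWF")
  xs <- seq(0, max(x), length.out = 512)
  if (is(fit, "GammaMixtureFit")) {
    m <- fit@model
    graphics::lines(xs, dGammaMixture(xs, m), col = "darkgreen", lwd = 2)
    graphics::lines(xs, m@lambda * dgamma(xs, m@comp1@shape,
                                          scale = m@comp1@scale),
                    col = "firebrick", lty = 2)
    graphics::lines(xs, (1 - m@lambda) * dgamma(xs, m@comp2@shape,
                                                scale = m@comp2@scale),
                    col = "steelblue", lty = 2)
  } else {
    graphics::lines(xs, dgamma(xs, fit@component@shape,
                               scale = fit@component@scale),
                    col = "darkgreen", lwd = 2)
  }
  invisible(NULL)
}
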