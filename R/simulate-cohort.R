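# Synthetic patient cohorts with a known linear thickness model.

# Sampling rules for predictor distributions. Each rule is a list with a
# `dist` element:
#   list(dist = "normal", mean, sd, lower = -Inf, upper = Inf)
#   list(dist = "uniform", min, max)
#   list(dist = "binary", p)              (0/1 indicator)
#   list(dist = "surrogate", of, offset = 0, sd)  (noisy copy of another
#                                                  already-sampled column)
samplePredictor <- function(rule, n, sampled) {
  switch(rule$dist,
         normal = {
           lower <- if (is.null(rule$lower)) -Inf else rule$lower
           upper <- if (is.null(rule$upper)) Inf else rule$upper
           x <- rnorm(n, rule$mean, rule$sd)
           bad <- x < lower | x > upper
           guard <- 0L
           while (any(bad)) {
             x[bad] <- rnorm(sum(bad), rule$mean, rule$sd)
             bad <- x < lower | x > upper
             guard <- guard + 1L
             if (guard > 1000L)
               stop("truncated-normal rejection sampling failed to terminate")
           }
           x
         },
         uniform = runif(n, rule$min, rule$max),
         binary = as.numeric(runif(n) < rule$p),
         surrogate = {
           base <- sampled[[rule$of]]
           if (is.null(base))
             stop("surrogate rule refers to '", rule$of,
                  "', which is not sampled yet")
           offset <- if (is.null(rule$offset)) 0 else rule$offset
           base + offset + rnorm(n, 0, rule$sd)
         },
         stop("unknown distribution kind: ", rule$dist))
}

#' Specification for a synthetic patient cohort
#'
#' Describes one study group: how each per-subject feature is sampled
#' and the linear model
#' \eqn{thickness = \beta_0 + \sum_j \beta_j x_j + \epsilon},
#' \eqn{\epsilon \sim N(0, noiseSD^2)}, that generates cortical
#' thickness. Every name in `trueCoefficients` other than
#' `"(Intercept)"` must be a sampled predictor.
#'
#' @param nSubjects number of subjects (at least one more than the
#'   number of predictors, and at least 2).
#' @param groupLabel `"RRMS"` or `"SPMS"`.
#' @param trueCoefficients named numeric vector including
#'   `"(Intercept)"`, in mm of thickness per predictor unit.
#' @param noiseSD residual SD of thickness, mm.
#' @param predictorDistributions named list of sampling rules; see
#'   Details in [makeCohort()].
#' @param seed integer RNG seed.
#' @return A [CohortSpec-class].
#' @seealso [rrmsCohortSpec()], [spmsCohortSpec()], [makeCohort()]
#' @export
cohortSpec <- function(nSubjects, groupLabel = "RRMS", trueCoefficients,
                       noiseSD, predictorDistributions, seed = 1L) {
  new("CohortSpec", nSubjects = as.integer(nSubjects),
      groupLabel = groupLabel, trueCoefficients = trueCoefficients,
      noiseSD = noiseSD, predictorDistributions = predictorDistributions,
      seed = as.integer(seed))
}

# Feature distributions emulating the published cohort demographics:
# mixture parameters around the reference mixture, mask-derived MWF
# means as noisy surrogates of the corresponding modes (a gamma
# component's mean exceeds its mode), and age/duration/treatment spreads
# matching the group summaries.
rrmsDistributions <- function() {
  list(m1 = list(dist = "normal", mean = 0.06, sd = 0.015, lower = 0.02),
       m2 = list(dist = "normal", mean = 0.17, sd = 0.015, lower = 0.05),
       lambda = list(dist = "normal", mean = 0.35, sd = 0.11,
                     lower = 0.02, upper = 0.98),
       mean_lesion_mwf = list(dist = "surrogate", of = "m1",
                              offset = 0.05, sd = 0.008),
       mean_nawm_mwf = list(dist = "surrogate", of = "m2",
                            offset = 0.04, sd = 0.008),
       age = list(dist = "normal", mean = 40.3, sd = 9.7, lower = 18),
       gender = list(dist = "binary", p = 90 / 134),
       dd = list(dist = "normal", mean = 7.7, sd = 7.3, lower = 0),
       dmt = list(dist = "normal", mean = 4.2, sd = 4.1, lower = 0))
}

spmsDistributions <- function() {
  list(m1 = list(dist = "normal", mean = 0.050, sd = 0.010, lower = 0.015),
       m2 = list(dist = "normal", mean = 0.145, sd = 0.020, lower = 0.05),
       lambda = list(dist = "normal", mean = 0.55, sd = 0.12,
                     lower = 0.02, upper = 0.98),
       mean_lesion_mwf = list(dist = "surrogate", of = "m1",
                              offset = 0.05, sd = 0.008),
       mean_nawm_mwf = list(dist = "surrogate", of = "m2",
                            offset = 0.04, sd = 0.008),
       age = list(dist = "normal", mean = 57.4, sd = 7.8, lower = 25),
       gender = list(dist = "binary", p = 16 / 23),
       dd = list(dist = "normal", mean = 21.7, sd = 11.0, lower = 0),
       dmt = list(dist = "normal", mean = 10.6, sd = 6.1, lower = 0))
}

#' Default cohort specifications for the two disease stages
#'
#' Ready-made [CohortSpec-class] objects emulating the two study groups.
#' The relapsing-remitting group (134 subjects) generates cortical
#' thickness from \eqn{m_1} (coefficient 1.56 mm per MWF unit),
#' \eqn{\lambda} (-0.30 mm) and age (-0.0031 mm/year); the
#' secondary-progressive group (23 subjects) from \eqn{m_2} alone
#' (4.72 mm per MWF unit). Intercepts centre mean thickness at 2.46 and
#' 2.27 mm respectively, and the residual SDs (0.116 and 0.104 mm) are
#' set so the signal explains roughly 16% and 45% of thickness variance
#' given the default predictor spreads.
#'
#' @param nSubjects number of subjects.
#' @param seed integer RNG seed.
#' @return A [CohortSpec-class].
#' @export
rrmsCohortSpec <- function(nSubjects = 134L, seed = 1L) {
  cohortSpec(nSubjects, "RRMS",
             trueCoefficients = c(`(Intercept)` = 2.596, m1 = 1.56,
                                  lambda = -0.30, age = -0.0031),
             noiseSD = 0.1155,
             predictorDistributions = rrmsDistributions(), seed = seed)
}

#' @rdname rrmsCohortSpec
#' @export
spmsCohortSpec <- function(nSubjects = 23L, seed = 1L) {
  cohortSpec(nSubjects, "SPMS",
             trueCoefficients = c(`(Intercept)` = 1.5856, m2 = 4.72),
             noiseSD = 0.104,
             predictorDistributions = spmsDistributions(), seed = seed)
}

#' Generate a synthetic cohort table
#'
#' Samples every predictor from its distribution rule, then generates
#' cortical thickness from the linear model in `trueCoefficients` plus
#' Gaussian noise. Reproducible under the spec's seed.
#'
#' Distribution rules are named lists: `normal` (mean, sd, optional
#' truncation bounds, sampled by rejection), `uniform` (min, max),
#' `binary` (probability of 1) and `surrogate` (a noisy shifted copy of
#' an already-sampled column, used for the mask-derived MWF means which
#' track the mixture modes).
#'
#' @param spec a [CohortSpec-class].
#' @return A data frame with columns `subject_id`, `group`, `m1`, `m2`,
#'   `lambda`, `mean_lesion_mwf`, `mean_nawm_mwf`, `age`, `gender`,
#'   `dd`, `dmt`, `cortical_thickness` (plus any extra sampled
#'   predictors).
#' @examples
#' head(makeCohort(rrmsCohortSpec(seed = 1)))
#' @export
makeCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  coefNames <- setdiff(names(spec@trueCoefficients), "(Intercept)")
  unknown <- setdiff(coefNames, names(spec@predictorDistributions))
  if (length(unknown))
    stop("trueCoefficients refer to unsampled predictor(s): ",
         paste(unknown, collapse = ", "))
  n <- spec@nSubjects
  withSeed(spec@seed, {
    sampled <- list()
    for (nm in names(spec@predictorDistributions)) {
      sampled[[nm]] <- samplePredictor(spec@predictorDistributions[[nm]],
                                       n, sampled)
    }
    thickness <- rep(spec@trueCoefficients[["(Intercept)"]], n)
    for (nm in coefNames)
      thickness <- thickness + spec@trueCoefficients[[nm]] * sampled[[nm]]
    thickness <- thickness + rnorm(n, 0, spec@noiseSD)
    canonical <- c("m1", "m2", "lambda", "mean_lesion_mwf",
                   "mean_nawm_mwf", "age", "gender", "dd", "dmt")
    ordered <- c(intersect(canonical, names(sampled)),
                 setdiff(names(sampled), canonical))
    out <- data.frame(
      subject_id = sprintf("%s%03d", substr(spec@groupLabel, 1, 1), 1:n),
      group = spec@groupLabel,
      stringsAsFactors = FALSE)
    for (nm in ordered) out[[nm]] <- sampled[[nm]]
    out$cortical_thickness <- thickness
    out
  })
}
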