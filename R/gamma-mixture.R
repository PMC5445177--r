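# Gamma components, mixture models, their densities and summaries.

#' Construct a gamma component
#'
#' @param shape positive shape \eqn{\alpha}.
#' @param scale positive scale \eqn{\beta} (MWF units).
#' @return A [GammaComponent-class].
#' @examples
#' gammaComponent(shape = 2, scale = 0.06)
#' @export
gammaComponent <- function(shape, scale) {
  new("GammaComponent", shape = as.numeric(shape), scale = as.numeric(scale))
}

#' Mode of a gamma component
#'
#' The most frequent value of a gamma distribution,
#' \eqn{m = (\alpha - 1)\beta} when \eqn{\alpha > 1} and 0 otherwise
#' (the density is monotonically decreasing for \eqn{\alpha \le 1}).
#'
#' @param object a [GammaComponent-class].
#' @return The mode, in MWF units.
#' @examples
#' componentMode(gammaComponent(2, 0.06))   # 0.06
#' componentMode(gammaComponent(0.8, 0.1))  # 0: monotone density
#' @rdname componentMode
#' @export
setMethod("componentMode", "GammaComponent", function(object) {
  max(0, (object@shape - 1) * object@scale)
})

#' Construct a two-component gamma mixture model
#'
#' Components are stored in canonical order, low mode first; if the
#' arguments arrive in the opposite order they are swapped and `lambda`
#' is replaced by `1 - lambda` so that it always weighs the low-mode
#' component. Ties in the mode (e.g. both shapes \eqn{\le 1}) are broken
#' by the component mean.
#'
#' @param lambda mixing ratio in \eqn{[0,1]}: weight of the low-mode
#'   component.
#' @param comp1,comp2 [GammaComponent-class] objects.
#' @return A [GammaMixtureModel-class].
#' @examples
#' gammaMixtureModel(0.25, gammaComponent(2, 0.06), gammaComponent(5, 0.0425))
#' @export
gammaMixtureModel <- function(lambda, comp1, comp2) {
  m1 <- componentMode(comp1)
  m2 <- componentMode(comp2)
  swap <- if (m1 != m2) m1 > m2 else
    comp1@shape * comp1@scale > comp2@shape * comp2@scale
  if (swap) {
    tmp <- comp1; comp1 <- comp2; comp2 <- tmp
    lambda <- 1 - lambda
  }
  new("GammaMixtureModel", lambda = as.numeric(lambda),
      comp1 = comp1, comp2 = comp2)
}

#' Reference white-matter MWF mixture
#'
#' A canonical two-component mixture with modes 0.06 (lesion-like) and
#' 0.17 (NAWM-like) MWF and shapes 2 and 5, the illustrative parameter
#' set used throughout the package's examples and synthetic defaults.
#' The scales follow from mode \eqn{= (\alpha-1)\beta}.
#'
#' @param lambda mixing ratio of the low-MWF component.
#' @return A [GammaMixtureModel-class].
#' @examples
#' referenceMixture()          # lambda 0.25: mostly NAWM
#' referenceMixture(0.75)      # lambda 0.75: mostly abnormal WM
#' @export
referenceMixture <- function(lambda = 0.25) {
  gammaMixtureModel(lambda,
                    gammaComponent(shape = 2, scale = 0.06 / (2 - 1)),
                    gammaComponent(shape = 5, scale = 0.17 / (5 - 1)))
}

#' @rdname accessors
#' @param object a [GammaMixtureModel-class].
#' @return `mixingRatio`: the weight of the low-mode component;
#'   `lowComponent` / `highComponent`: the corresponding
#'   [GammaComponent-class].
#' @export
setMethod("mixingRatio", "GammaMixtureModel", function(object) object@lambda)

#' @rdname accessors
#' @export
setMethod("lowComponent", "GammaMixtureModel", function(object) object@comp1)

#' @rdname accessors
#' @export
setMethod("highComponent", "GammaMixtureModel", function(object) object@comp2)

#' Density, distribution function and sampling for the gamma mixture
#'
#' `dGammaMixture` and `pGammaMixture` evaluate the mixture pdf and cdf;
#' `sampleGammaMixture` draws from the mixture by sampling the component
#' label with probability `lambda` and then the component value.
#'
#' @param x,q numeric vector of MWF values.
#' @param model a [GammaMixtureModel-class].
#' @param n number of draws (>= 1).
#' @param seed optional integer seed; when given, draws are reproducible
#'   and the caller's RNG state is left untouched.
#' @return `dGammaMixture`, `pGammaMixture`: numeric vector;
#'   `sampleGammaMixture`: numeric vector of `n` draws.
#' @examples
#' m <- referenceMixture()
#' integrate(dGammaMixture, 0, Inf, model = m)  # 1
#' x <- sampleGammaMixture(m, 1000, seed = 1)
#' @export
dGammaMixture <- function(x, model) {
  model@lambda * dgamma(x, model@comp1@shape, scale = model@comp1@scale) +
    (1 - model@lambda) * dgamma(x, model@comp2@shape,
                                scale = model@comp2@scale)
}

#' @rdname dGammaMixture
#' @export
pGammaMixture <- function(q, model) {
  model@lambda * pgamma(q, model@comp1@shape, scale = model@comp1@scale) +
    (1 - model@lambda) * pgamma(q, model@comp2@shape,
                                scale = model@comp2@scale)
}

#' @rdname dGammaMixture
#' @export
sampleGammaMixture <- function(model, n, seed = NULL) {
  stopifnot(is(model, "GammaMixtureModel"))
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be a count >= 1")
  withSeed(seed, {
    z <- runif(n) < model@lambda
    out <- numeric(n)
    n1 <- sum(z)
    out[z] <- rgamma(n1, model@comp1@shape, scale = model@comp1@scale)
    out[!z] <- rgamma(n - n1, model@comp2@shape, scale = model@comp2@scale)
    out
  })
}

#' Subject-level reduction of a mixture fit
#'
#' Extracts the three-number summary carried into group analyses: the
#' low-component mode \eqn{m_1}, the high-component mode \eqn{m_2} and
#' the mixing ratio \eqn{\lambda}. The canonical component ordering
#' guarantees \eqn{m_1 \le m_2} irrespective of initialization. When a
#' fitted shape is \eqn{\le 1} the corresponding mode is truncated at 0
#' and a warning is raised, since the component density is then monotone.
#'
#' @param fit a [GammaMixtureFit-class] (passing a single-gamma fit is an
#'   error: consult the model selection outcome first).
#' @return Named numeric `c(m1, m2, lambda)`.
#' @seealso [fitGammaMixture()], [penalizedLRT()]
#' @rdname summarizeFit
#' @export
setMethod("summarizeFit", "GammaMixtureFit", function(fit) {
  model <- fit@model
  if (model@comp1@shape <= 1 || model@comp2@shape <= 1)
    warning("fitted shape <= 1: mode truncated at 0 (boundary)")
  c(m1 = componentMode(model@comp1),
    m2 = componentMode(model@comp2),
    lambda = model@lambda)
})

#' @rdname summarizeFit
#' @export
setMethod("summarizeFit", "SingleGammaFit", function(fit) {
  stop("single-gamma fit has no mixture summary; use the model-selection ",
       "outcome (penalizedLRT) to decide whether the mixture applies")
})

setMethod("show", "GammaComponent", function(object) {
  cat(sprintf("GammaComponent: shape %.4g, scale %.4g (mode %.4g)\n",
              object@shape, object@scale, componentMode(object)))
})

setMethod("show", "GammaMixtureModel", function(object) {
  cat("GammaMixtureModel (two-component gamma mixture)\n")
  cat(sprintf("  lambda (low-mode weight): %.4f\n", object@lambda))
  cat(sprintf("  comp1: shape %.4g, scale %.4g  -> m1 = %.4g\n",
              object@comp1@shape, object@comp1@scale,
              componentMode(object@comp1)))
  cat(sprintf("  comp2: shape %.4g, scale %.4g  -> m2 = %.4g\n",
              object@comp2@shape, object@comp2@scale,
              componentMode(object@comp2)))
})

setMethod("show", "GammaMixtureFit", function(object) {
  cat(sprintf(
    "GammaMixtureFit: n = %d (%d non-positive dropped), logLik = %.3f\n",
    object@nObs, object@nDropped, object@logLik))
  cat(sprintf("  %d EM iterations, converged: %s\n",
              object@nIter, object@converged))
  show(object@model)
})

setMethod("show", "SingleGammaFit", function(object) {
  cat(sprintf(
    "SingleGammaFit: n = %d (%d non-positive dropped), logLik = %.3f\n",
    object@nObs, object@nDropped, object@logLik))
  show(object@component)
})

setMethod("show", "MixtureSelection", function(object) {
  cat("MixtureSelection (penalized LRT, parametric bootstrap)\n")
  cat(sprintf("  statistic = %.3f, p = %.4g (B = %d, alpha = %.3g)\n",
              object@statistic, object@pValue, object@nBootstrap,
              object@alpha))
  cat(sprintf("  chosen model: %s\n", object@chosen))
})
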