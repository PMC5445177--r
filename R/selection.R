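# Choice between the single gamma and the gamma mixture by a penalized
# likelihood ratio test with a parametric bootstrap null.

#' Penalized likelihood ratio test for one vs. two gamma components
#'
#' Compares the two-component gamma mixture with the single gamma on the
#' same data. The classical LRT is irregular here (the null places
#' \eqn{\lambda} on the boundary of the parameter space), so the mixture
#' log-likelihood is penalized with \eqn{\log(4\lambda(1-\lambda))},
#' which vanishes at \eqn{\lambda = 1/2} and discounts boundary fits, and
#' the null distribution of the statistic
#' \deqn{T = 2\,[(\ell_{mix} + \log(4\hat\lambda(1-\hat\lambda))) - \ell_{single}]}
#' is calibrated by a parametric bootstrap: `nBootstrap` datasets of the
#' same size are simulated from the fitted single gamma and both models
#' are refitted on each (with the same EM settings), giving replicate
#' statistics \eqn{T^{(b)}}. The p-value is the exceedance proportion
#' \eqn{(1 + \#\{T^{(b)} \ge T\})/(B+1)}, so its floor is
#' \eqn{1/(B+1)}. The mixture is chosen when \eqn{p < } `alpha`.
#'
#' Replicates on which the mixture fit collapses contribute
#' \eqn{T^{(b)} = -\infty} (no mixture evidence).
#'
#' @param single a [SingleGammaFit-class] on `values`.
#' @param mixture a [GammaMixtureFit-class] on `values`.
#' @param values the data both fits were produced on.
#' @param nBootstrap number of bootstrap replicates (at least 19, for
#'   p-value resolution).
#' @param alpha significance level of the choice.
#' @param seed integer seed for the bootstrap.
#' @param fitTol,fitMaxIter,polish EM settings used for the per-replicate
#'   refits (defaults match [fitGammaMixture()]).
#' @return A [MixtureSelection-class].
#' @examples
#' x <- sampleGammaMixture(referenceMixture(), 2000, seed = 1)
#' sel <- penalizedLRT(fitSingleGamma(x), fitGammaMixture(x), x,
#'                     nBootstrap = 39, seed = 1)
#' sel@chosen
#' @export
penalizedLRT <- function(single, mixture, values, nBootstrap = 199L,
                         alpha = 0.05, seed = 1L, fitTol = 1e-8,
                         fitMaxIter = 2000L, polish = TRUE) {
  stopifnot(is(single, "SingleGammaFit"), is(mixture, "GammaMixtureFit"))
  if (nBootstrap < 19L)
    stop("'nBootstrap' must be at least 19 for usable p-value resolution")
  cleaned <- dropNonPositive(values)
  x <- cleaned$values
  if (single@nObs != length(x) || mixture@nObs != length(x))
    stop("'single' and 'mixture' must be fits of the same 'values'")
  stat <- penalizedStat(mixture@logLik, mixingRatio(mixture@model),
                        single@logLik)
  shape <- single@component@shape
  scale <- single@component@scale
  n <- length(x)
  bootStats <- withSeed(seed, {
    vapply(seq_len(nBootstrap), function(b) {
      xb <- rgamma(n, shape, scale = scale)
      sb <- fitSingleGamma(xb)
      mb <- tryCatch(
        fitGammaMixture(xb, tol = fitTol, maxIter = fitMaxIter,
                        polish = polish),
        error = function(e) NULL)
      if (is.null(mb)) -Inf
      else penalizedStat(mb@logLik, mixingRatio(mb@model), sb@logLik)
    }, numeric(1))
  })
  p <- (1 + sum(bootStats >= stat)) / (nBootstrap + 1)
  new("MixtureSelection", statistic = stat, pValue = p,
      chosen = if (p < alpha) "mixture" else "single",
      nBootstrap = as.integer(nBootstrap), alpha = alpha,
      bootStats = bootStats)
}

# 2 * (penalized mixture log-likelihood - single log-likelihood).
# The penalty log(4 lambda (1 - lambda)) is <= 0, maximal at 1/2.
penalizedStat <- function(mixLogLik, lambda, singleLogLik) {
  2 * ((mixLogLik + log(4 * lambda * (1 - lambda))) - singleLogLik)
}
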