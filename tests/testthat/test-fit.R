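# Maximum-likelihood fitting: single gamma and the two-component EM.

test_that("single-gamma ML recovers parameters and beats a parameter grid", {
  x <- withr::with_seed(1, rgamma(1e5, shape = 3, scale = 0.05))
  fit <- fitSingleGamma(x)
  expect_lt(abs(fit@component@shape - 3), 0.05)
  expect_lt(abs(fit@component@scale - 0.05), 0.002)
  expect_true(fit@converged)

  # the fitted log-likelihood dominates a 200 x 200 parameter grid
  y <- withr::with_seed(2, rgamma(200, shape = 4, scale = 0.04))
  fit2 <- fitSingleGamma(y)
  shapes <- seq(0.5, 20, length.out = 200)
  scales <- seq(0.001, 0.2, length.out = 200)
  sumLog <- sum(log(y)); sumY <- sum(y); n <- length(y)
  gridBest <- max(vapply(shapes, function(a) {
    max((a - 1) * sumLog - sumY / scales - n * lgamma(a) -
          n * a * log(scales))
  }, numeric(1)))
  expect_gte(fit2@logLik, gridBest)
})

test_that("single-gamma ML agrees with an independent ML implementation", {
  x <- withr::with_seed(3, rgamma(2000, shape = 2.5, scale = 0.07))
  fit <- fitSingleGamma(x)
  ref <- fitdistrplus::fitdist(x, "gamma")  # (shape, rate) parameterization
  expect_equal(fit@component@shape, unname(ref$estimate["shape"]),
               tolerance = 1e-4)
  expect_equal(fit@component@scale, 1 / unname(ref$estimate["rate"]),
               tolerance = 1e-4)
})

test_that("single-gamma fit validates its input", {
  expect_error(fitSingleGamma(c(0.1, 0.2, -0.01, 0.3)), "negative")
  expect_error(fitSingleGamma(rep(0.1, 100)), "identical")
  expect_error(fitSingleGamma(c(0.1, 0.2)), "at least 10")
  # zeros are excluded and counted, not an error
  x <- withr::with_seed(4, rgamma(1000, 3, scale = 0.05))
  fit <- fitSingleGamma(c(x, 0, 0, 0))
  expect_identical(fit@nDropped, 3L)
  expect_identical(fit@nObs, 1000L)
})

test_that("EM separates two point-mass-like clusters at the counting rate", {
  # tight components at 0.05 and 0.20; lambda equals the realized
  # cluster proportion (counting oracle)
  tight <- gammaMixtureModel(0.3,
                             gammaComponent(4e4, 0.05 / (4e4 - 1)),
                             gammaComponent(4e4, 0.20 / (4e4 - 1)))
  x <- sampleGammaMixture(tight, 5000, seed = 5)
  frac <- mean(x < 0.125)
  fit <- fitGammaMixture(x)
  expect_lt(abs(mixingRatio(fit@model) - frac), 0.005)
})

test_that("EM log-likelihood is monotone and ascends from any start", {
  m <- refMix()
  x <- sampleGammaMixture(m, 20000, seed = 6)
  fit <- fitGammaMixture(x)
  expect_true(all(diff(fit@trace) >= -1e-10 * abs(fit@trace[-1])))

  # starting at the truth can only improve the likelihood
  ll0 <- mixLogLik(x, 0.25, 2, 0.06, 5, 0.0425)
  fitT <- fitGammaMixture(x, init = m)
  expect_gte(fitT@logLik, ll0)

  # the quasi-Newton refinement never falls below plain EM
  fitEM <- fitGammaMixture(x, polish = FALSE)
  expect_gte(fit@logLik, fitEM@logLik)
})

test_that("EM beats 1000 random parameter draws evaluated directly", {
  x <- sampleGammaMixture(refMix(), 400, seed = 7)
  fit <- fitGammaMixture(x)
  best <- withr::with_seed(8, {
    max(vapply(1:1000, function(i) {
      mixLogLik(x, runif(1), exp(runif(1, log(0.5), log(30))),
                exp(runif(1, log(0.005), log(0.2))),
                exp(runif(1, log(0.5), log(30))),
                exp(runif(1, log(0.005), log(0.2))))
    }, numeric(1)))
  })
  expect_gte(fit@logLik, best)
})

test_that("the subject summary is invariant to component label order", {
  x <- sampleGammaMixture(refMix(), 5000, seed = 9)
  init1 <- gammaMixtureModel(0.4, gammaComponent(2, 0.05),
                             gammaComponent(6, 0.03))
  init2 <- gammaMixtureModel(0.6, gammaComponent(6, 0.03),
                             gammaComponent(2, 0.05))  # swapped labels
  s1 <- summarizeFit(fitGammaMixture(x, init = init1))
  s2 <- summarizeFit(fitGammaMixture(x, init = init2))
  expect_equal(s1, s2, tolerance = 1e-6)
  expect_lte(s1[["m1"]], s1[["m2"]])
})

test_that("mixing-ratio error shrinks with sample size for separated components", {
  wellSep <- gammaMixtureModel(0.3, gammaComponent(20, 0.05 / 19),
                               gammaComponent(60, 0.20 / 59))
  medianDev <- vapply(c(1e3, 1e4, 1e5), function(n) {
    median(vapply(1:3, function(s) {
      fit <- fitGammaMixture(sampleGammaMixture(wellSep, n, seed = s))
      abs(mixingRatio(fit@model) - 0.3)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(medianDev) < 0))
})

test_that("EM edge cases are reported, not silently mishandled", {
  x <- withr::with_seed(10, rgamma(500, 3, scale = 0.05))
  # non-convergence is a flag, not an exception
  f <- fitGammaMixture(x, maxIter = 2, polish = FALSE)
  expect_false(f@converged)
  # an initialization far outside the data collapses a component
  away <- gammaMixtureModel(0.5, gammaComponent(1e6, 1e-8),
                            gammaComponent(3, 0.05))
  expect_error(fitGammaMixture(x, init = away), "collapse")
  # sample-size and domain guards
  expect_error(fitGammaMixture(x[1:20]), "at least 50")
  expect_error(fitGammaMixture(c(x, -0.01)), "negative")
  # a summary of a single fit points back to model selection
  expect_error(summarizeFit(fitSingleGamma(x)), "selection")
  # shape <= 1 gives a truncated mode with a boundary warning
  lowShape <- new("GammaMixtureFit",
                  model = gammaMixtureModel(0.3, gammaComponent(0.8, 0.05),
                                            gammaComponent(5, 0.0425)),
                  logLik = 0, trace = 0, nIter = 1L, converged = TRUE,
                  nObs = 100L, nDropped = 0L)
  expect_warning(s <- summarizeFit(lowShape), "boundary")
  expect_equal(s[["m1"]], 0)
})
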