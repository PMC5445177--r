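# Gamma components, mixture model, density/CDF and sampling.

test_that("component mode follows the (shape-1)*scale formula with truncation at 0", {
  expect_equal(componentMode(gammaComponent(2, 0.06)), 0.06)
  expect_equal(componentMode(gammaComponent(1, 0.1)), 0)
  expect_equal(componentMode(gammaComponent(0.7, 0.1)), 0)
  # grid-argmax oracle: the mode maximizes the density
  comp <- gammaComponent(5, 0.0425)
  expect_equal(componentMode(comp), 0.17)
  grid <- seq(0, 0.5, length.out = 10001)
  argmax <- grid[which.max(dgamma(grid, comp@shape, scale = comp@scale))]
  expect_lt(abs(argmax - componentMode(comp)), diff(grid[1:2]) + 1e-12)
})

test_that("component and mixture validity is enforced", {
  expect_error(gammaComponent(-1, 0.1), "shape")
  expect_error(gammaComponent(2, 0), "scale")
  expect_error(gammaMixtureModel(1.5, gammaComponent(2, 0.06),
                                 gammaComponent(5, 0.0425)), "lambda")
})

test_that("mixture components are stored in canonical low-mode-first order", {
  lowC <- gammaComponent(2, 0.06)
  highC <- gammaComponent(5, 0.0425)
  a <- gammaMixtureModel(0.25, lowC, highC)
  b <- gammaMixtureModel(0.75, highC, lowC)  # same mixture, swapped storage
  expect_equal(mixingRatio(a), mixingRatio(b))
  expect_equal(componentMode(lowComponent(a)), 0.06)
  expect_equal(componentMode(highComponent(a)), 0.17)
  expect_equal(componentMode(lowComponent(b)), 0.06)
})

test_that("the reference mixture has the canonical modes and mixing ratio", {
  m <- refMix()
  expect_equal(componentMode(lowComponent(m)), 0.06)
  expect_equal(componentMode(highComponent(m)), 0.17)
  expect_equal(mixingRatio(m), 0.25)
})

test_that("the mixture pdf integrates to 1 and matches the closed-form CDF", {
  for (lam in c(0.1, 0.25, 0.75)) {
    m <- refMix(lam)
    expect_equal(integrate(dGammaMixture, 0, Inf, model = m,
                           rel.tol = 1e-10)$value, 1, tolerance = 1e-6)
  }
  m <- refMix()
  for (q in c(0.03, 0.1, 0.25)) {
    expect_equal(pGammaMixture(q, m),
                 integrate(dGammaMixture, 0, q, model = m,
                           rel.tol = 1e-10)$value, tolerance = 1e-8)
  }
})

test_that("sampling matches the mixture distribution", {
  # degenerate lambda = 1: mean within 3 SE of the low component's mean
  m1only <- refMix(1)
  x <- sampleGammaMixture(m1only, 10000, seed = 1)
  comp <- lowComponent(m1only)
  se <- comp@scale * sqrt(comp@shape) / sqrt(10000)
  expect_lt(abs(mean(x) - comp@shape * comp@scale), 3 * se)

  # degenerate lambda = 0: every draw is at least as likely under the
  # high component as the total low-component share of the density is 0
  m2only <- refMix(0)
  y <- sampleGammaMixture(m2only, 5000, seed = 2)
  expect_equal(dGammaMixture(y, m2only),
               dgamma(y, highComponent(m2only)@shape,
                      scale = highComponent(m2only)@scale))

  # antimode mass oracle: fraction of draws below the density minimum
  # between the two modes matches quadrature of the pdf, within 3 SE
  m <- refMix()
  anti <- optimize(dGammaMixture, c(0.06, 0.17), model = m)$minimum
  pAnti <- integrate(dGammaMixture, 0, anti, model = m,
                     rel.tol = 1e-10)$value
  z <- sampleGammaMixture(m, 1e5, seed = 3)
  se <- sqrt(pAnti * (1 - pAnti) / 1e5)
  expect_lt(abs(mean(z < anti) - pAnti), 3 * se)
})

test_that("sampling is seed-reproducible and validates n", {
  m <- refMix()
  expect_identical(sampleGammaMixture(m, 100, seed = 7),
                   sampleGammaMixture(m, 100, seed = 7))
  expect_error(sampleGammaMixture(m, 0, seed = 1), "n")
})

test_that("MWF is the myelin-water share of the total signal", {
  expect_equal(compartmentsToMWF(0, 5, 5), 0)
  expect_equal(compartmentsToMWF(1, 1, 0), 0.5)
  expect_equal(compartmentsToMWF(0.1388, 0.8612, 0), 0.1388)
  expect_equal(compartmentsToMWF(c(1, 2), c(1, 2), c(2, 4)), c(0.25, 0.25))
  expect_error(compartmentsToMWF(0, 0, 0), "invalid voxel")
  expect_error(compartmentsToMWF(-1, 1, 1), "nonnegative")
})
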