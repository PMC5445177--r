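# Shared fixtures, built in code at test time.

# Canonical two-component mixture used across tests: modes 0.06 / 0.17,
# shapes 2 / 5, low-component weight 0.25.
refMix <- function(lambda = 0.25) referenceMixture(lambda)

# Small grid for cheap volume tests.
smallSpec <- function(seed, ...) {
  volumeSpec(gridShape = c(32L, 32L, 16L), lesionRadiusRange = c(2, 4),
             seed = seed, ...)
}

# A RegressionFit carrying given coefficients (for interpretation
# helpers that only need the coefficient table).
regFitWith <- function(coefs, predictors = setdiff(names(coefs),
                                                   "(Intercept)")) {
  new("RegressionFit", predictors = predictors, coefficients = coefs,
      se = rep(NA_real_, length(coefs)), pValues = rep(NA_real_,
                                                       length(coefs)),
      r2 = NA_real_, adjR2 = NA_real_, cvMSE = NA_real_, n = 0L,
      response = "cortical_thickness")
}

# Independent mixture log-likelihood (plain R, no EM machinery).
mixLogLik <- function(x, lambda, a1, b1, a2, b2) {
  sum(log(lambda * dgamma(x, a1, scale = b1) +
            (1 - lambda) * dgamma(x, a2, scale = b2)))
}
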