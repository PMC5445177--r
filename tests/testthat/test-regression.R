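# OLS, exhaustive CV subset search, LMG importance, Welch test and
# coefficient interpretation.

test_that("OLS matches the normal-equations oracle on a hand dataset", {
  tab <- data.frame(x1 = c(1, 2, 3, 4, 5),
                    x2 = c(0.2, 0.1, 0.4, 0.3, 0.5),
                    cortical_thickness = c(2.1, 2.3, 2.0, 2.4, 2.2))
  fit <- fitOLS(tab, c("x1", "x2"))
  X <- cbind(1, tab$x1, tab$x2)
  beta <- solve(crossprod(X), crossprod(X, tab$cortical_thickness))
  expect_equal(unname(fit@coefficients), drop(beta), tolerance = 1e-12)
  # adjusted R2 from its definition
  expect_equal(fit@adjR2, 1 - (1 - fit@r2) * (5 - 1) / (5 - 2 - 1))
})

test_that("OLS handles degenerate designs informatively", {
  tab <- data.frame(x1 = 1:6, x2 = 2 * (1:6), cortical_thickness = rnorm(6))
  expect_error(fitOLS(tab, c("x1", "x2")), "collinear")
  const <- data.frame(x1 = rnorm(10), cortical_thickness = rep(2.3, 10))
  f <- fitOLS(const, "x1")
  expect_equal(f@r2, 0)
  expect_equal(unname(f@coefficients["x1"]), 0, tolerance = 1e-10)
  expect_error(fitOLS(const, "nope"), "unknown")
  expect_error(fitOLS(const[1:2, ], "x1"), "need n")
})

test_that("exhaustive CV search enumerates all subsets and matches brute force", {
  co <- makeCohort(rrmsCohortSpec(40, seed = 1))
  cands <- c("m1", "lambda", "age")
  sel <- exhaustiveCVSelect(co, cands, k = 5, seed = 9)
  expect_identical(nrow(sel$ranking), 8L)  # 2^3 subsets

  # independent brute-force oracle with the same fold assignment
  n <- nrow(co)
  fold <- withr::with_seed(9, sample(rep_len(1:5, n)))
  subsets <- list(character(0), "age", "lambda", "m1", c("age", "lambda"),
                  c("age", "m1"), c("lambda", "m1"),
                  c("age", "lambda", "m1"))
  oracle <- vapply(subsets, function(s) {
    err <- numeric(n)
    for (f in 1:5) {
      test <- fold == f
      d <- co[, c(s, "cortical_thickness"), drop = FALSE]
      fml <- if (length(s)) paste("cortical_thickness ~",
                                  paste(s, collapse = "+"))
      else "cortical_thickness ~ 1"
      m <- lm(as.formula(fml), data = d[!test, , drop = FALSE])
      err[test] <- (d$cortical_thickness[test] -
                      predict(m, d[test, , drop = FALSE]))^2
    }
    mean(err)
  }, numeric(1))
  best <- subsets[[which.min(oracle)]]
  expect_setequal(sel$best@predictors, best)
  keys <- vapply(subsets, function(s) paste(sort(s), collapse = ","),
                 character(1))
  expect_equal(sel$ranking$cvMSE[match(keys, sel$ranking$subset)],
               oracle, tolerance = 1e-12)
  expect_error(exhaustiveCVSelect(co, cands, k = 50, seed = 1), "exceed")
  expect_error(exhaustiveCVSelect(co, character(0)), "nonempty")
})

test_that("the NAWM-flavored predictor drives the progressive-group model", {
  cands <- c("m1", "m2", "lambda", "age", "gender", "dd", "dmt")
  m2In <- vapply(1:20, function(s) {
    co <- makeCohort(spmsCohortSpec(seed = s))
    "m2" %in% exhaustiveCVSelect(co, cands, k = 10, seed = s)$best@predictors
  }, logical(1))
  expect_gte(mean(m2In), 0.9)
  # both predictor sets pick the NAWM-flavored surrogate pair
  co <- makeCohort(spmsCohortSpec(seed = 3))
  cmp <- comparePredictorSets(co, k = 10, seed = 3)
  expect_true("m2" %in% cmp$gamma$best@predictors)
  expect_true("mean_nawm_mwf" %in% cmp$mask$best@predictors)
})

test_that("the relapsing-group search most often lands on {m1, lambda, age}", {
  cands <- c("m1", "m2", "lambda", "age", "gender", "dd", "dmt")
  picks <- vapply(1:20, function(s) {
    co <- makeCohort(rrmsCohortSpec(seed = s))
    paste(sort(exhaustiveCVSelect(co, cands, k = 10,
                                  seed = s)$best@predictors),
          collapse = "+")
  }, character(1))
  modal <- names(sort(table(picks), decreasing = TRUE))[1]
  expect_identical(modal, "age+lambda+m1")
  expect_gte(mean(grepl("lambda", picks)), 0.9)
})

test_that("the mixture predictor set explains at least as much as the mask set", {
  better <- vapply(1:20, function(s) {
    co <- makeCohort(rrmsCohortSpec(seed = s))
    cmp <- comparePredictorSets(co, k = 10, seed = s)
    cmp$gamma$best@adjR2 >= cmp$mask$best@adjR2
  }, logical(1))
  expect_gte(mean(better), 0.8)
  # identical candidate sets give identical reports
  co <- makeCohort(rrmsCohortSpec(seed = 4))
  same <- comparePredictorSets(co, setGamma = c("m1", "age"),
                               setMask = c("m1", "age"), k = 10, seed = 4)
  expect_identical(same$better, "tie")
  expect_equal(same$gamma$best@adjR2, same$mask$best@adjR2)
})

test_that("LMG shares decompose R2 exactly", {
  co <- makeCohort(rrmsCohortSpec(seed = 5))
  im <- lmgImportance(co, c("m1", "lambda", "age"))
  expect_equal(sum(im$share), attr(im, "r2"), tolerance = 1e-8)
  expect_equal(sum(im$relative), 1, tolerance = 1e-12)
  expect_true(all(im$share >= 0))

  # a single predictor owns the whole R2
  one <- lmgImportance(co, "lambda")
  expect_equal(one$share, attr(one, "r2"), tolerance = 1e-12)

  # orthogonal predictors with equal marginal R2 split evenly
  tab <- data.frame(x1 = rep(c(1, -1), 10), x2 = rep(c(1, 1, -1, -1), 5))
  tab$cortical_thickness <- 2 + 0.1 * tab$x1 + 0.1 * tab$x2
  im2 <- lmgImportance(tab, c("x1", "x2"))
  expect_equal(im2$share[1], im2$share[2], tolerance = 1e-12)

  # random full-rank designs: decomposition exactness
  withr::with_seed(6, {
    for (i in 1:5) {
      tabR <- as.data.frame(matrix(rnorm(60 * 4), 60, 4))
      colnames(tabR) <- paste0("p", 1:4)
      tabR$cortical_thickness <- rnorm(60) + tabR$p1 - 0.5 * tabR$p3
      imR <- lmgImportance(tabR, paste0("p", 1:4))
      expect_equal(sum(imR$share), attr(imR, "r2"), tolerance = 1e-8)
    }
  })
  expect_error(lmgImportance(co, character(0)), "nonempty")
})

test_that("LMG importance reproduces the relapsing-group pattern", {
  # large cohort so the shares concentrate at their population values:
  # lambda strongest, age next, m1 smallest, all above 20%
  co <- makeCohort(rrmsCohortSpec(1000, seed = 4))
  im <- lmgImportance(co, c("m1", "lambda", "age"))
  rel <- setNames(im$relative, im$predictor)
  expect_true(all(rel > 0.2))
  expect_identical(names(which.max(rel)), "lambda")
})

test_that("Welch test matches the closed-form statistic", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5)
  w <- welchT(a, b)
  va <- var(a) / 3; vb <- var(b) / 5
  tOracle <- (mean(a) - mean(b)) / sqrt(va + vb)
  dfOracle <- (va + vb)^2 / (va^2 / 2 + vb^2 / 4)
  expect_equal(w$t, tOracle, tolerance = 1e-12)
  expect_equal(w$df, dfOracle, tolerance = 1e-12)
  expect_equal(w$p, 2 * pt(-abs(tOracle), dfOracle), tolerance = 1e-12)

  same <- welchT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welchT(1, c(1, 2)), "at least 2")
  expect_error(welchT(c(1, 1, 1), c(2, 2)), "zero variance")
})

test_that("whole-brain MWF differs between groups at the printed magnitudes", {
  ps <- vapply(1:20, function(s) withr::with_seed(s, {
    welchT(rnorm(134, 0.1388, 0.0205), rnorm(23, 0.1173, 0.0206))$p
  }), numeric(1))
  expect_gte(mean(ps < 0.05), 0.95)
  expect_gte(mean(ps < 0.001), 0.6)
})

test_that("adding a pure-noise predictor does not raise adjusted R2 in median", {
  deltas <- vapply(1:100, function(s) withr::with_seed(s, {
    co <- makeCohort(rrmsCohortSpec(seed = s + 300))
    co$noisep <- rnorm(nrow(co))
    fitOLS(co, c("m1", "lambda", "age", "noisep"))@adjR2 -
      fitOLS(co, c("m1", "lambda", "age"))@adjR2
  }), numeric(1))
  expect_lt(median(deltas), 0)
})

test_that("coefficients translate into per-0.05 mm predictor deltas", {
  fit <- regFitWith(c(`(Intercept)` = 2.6, m1 = 1.56, lambda = -0.30,
                      age = -0.0031))
  expect_equal(deltaForThicknessChange(fit, "m1"), 0.05 / 1.56)
  expect_equal(deltaForThicknessChange(fit, "lambda"), 0.05 / 0.30)
  expect_error(deltaForThicknessChange(fit, "m2"), "not a predictor")
  zero <- regFitWith(c(`(Intercept)` = 1, m1 = 0))
  expect_error(deltaForThicknessChange(zero, "m1"), "undefined")
})
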