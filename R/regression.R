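# Group analysis: OLS on feature subsets, exhaustive model search with
# k-fold cross-validation, LMG relative importance, Welch tests and
# coefficient interpretation.

# Numeric design matrix (intercept first) for a predictor subset, with a
# rank check that names the offending columns.
designMatrix <- function(table, predictors) {
  missing <- setdiff(predictors, colnames(table))
  if (length(missing))
    stop("unknown predictor(s): ", paste(missing, collapse = ", "))
  n <- nrow(table)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (length(predictors)) {
    P <- vapply(predictors, function(p) as.numeric(table[[p]]), numeric(n))
    X <- cbind(X, P)
    if (anyNA(P))
      stop("missing values in predictors: ",
           paste(predictors[colSums(is.na(P)) > 0], collapse = ", "))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear design: column(s) ", paste(aliased, collapse = ", "),
         " are linearly dependent on the others")
  }
  X
}

#' Ordinary least-squares fit of cortical thickness on a feature subset
#'
#' Fits the multivariate linear regression of `response` on the given
#' predictors (intercept always included) and reports the coefficient
#' table, \eqn{R^2} and adjusted
#' \eqn{R^2 = 1 - (1 - R^2)(n - 1)/(n - p - 1)}.
#'
#' @param table data frame of subject features (one row per subject).
#' @param predictors character vector of column names; may be empty for
#'   the intercept-only model.
#' @param response response column name.
#' @return A [RegressionFit-class] (slot `cvMSE` is `NA`).
#' @seealso [exhaustiveCVSelect()], [lmgImportance()]
#' @export
fitOLS <- function(table, predictors = character(),
                   response = "cortical_thickness") {
  if (!response %in% colnames(table))
    stop("unknown response: ", response)
  y <- as.numeric(table[[response]])
  n <- length(y)
  p <- length(predictors)
  if (n <= p + 1)
    stop("need n > number of predictors + 1")
  X <- designMatrix(table, predictors)
  fit <- lm.fit(X, y)
  res <- fit$residuals
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 0 else 1 - rss / tss
  adjR2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  sigma2 <- rss / (n - p - 1)
  XtXinv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(diag(XtXinv) * sigma2)[order(fit$qr$pivot)]
  names(se) <- colnames(X)
  coefs <- fit$coefficients
  tvals <- coefs / se
  pvals <- 2 * pt(abs(tvals), df = n - p - 1, lower.tail = FALSE)
  new("RegressionFit", predictors = as.character(predictors),
      coefficients = coefs, se = se, pValues = pvals,
      r2 = r2, adjR2 = adjR2, cvMSE = NA_real_, n = as.integer(n),
      response = response)
}

setMethod("show", "RegressionFit", function(object) {
  cat(sprintf("RegressionFit: %s ~ %s (n = %d)\n", object@response,
              if (length(object@predictors))
                paste(object@predictors, collapse = " + ") else "1",
              object@n))
  tab <- data.frame(estimate = object@coefficients, se = object@se,
                    p = object@pValues)
  print(signif(tab, 4))
  cat(sprintf("  R2 = %.4f, adjusted R2 = %.4f", object@r2, object@adjR2))
  if (!is.na(object@cvMSE))
    cat(sprintf(", CV MSE = %.5g mm^2", object@cvMSE))
  cat("\n")
})

# All subsets of the candidate set as a list of character vectors, in a
# deterministic order (by size, then lexicographic).
allSubsets <- function(candidates) {
  p <- length(candidates)
  subsets <- lapply(0:(2^p - 1), function(mask) {
    candidates[bitwAnd(mask, 2^(seq_len(p) - 1)) > 0]
  })
  ord <- order(lengths(subsets),
               vapply(subsets, function(s) paste(sort(s), collapse = ","),
                      character(1)))
  subsets[ord]
}

# k-fold CV mean squared error of an OLS model with a fixed fold
# assignment (shared across subsets so MSEs are comparable).
cvMSEForSubset <- function(X, y, fold, k) {
  err2 <- numeric(length(y))
  for (f in seq_len(k)) {
    test <- fold == f
    fit <- lm.fit(X[!test, , drop = FALSE], y[!test])
    pred <- X[test, , drop = FALSE] %*% fit$coefficients
    err2[test] <- (y[test] - pred)^2
  }
  mean(err2)
}

#' Exhaustive predictor-subset search with k-fold cross-validation
#'
#' Enumerates every subset of the candidate predictors (including the
#' intercept-only model), scores each by k-fold cross-validated mean
#' squared error with one seeded subject-level fold assignment shared
#' across all subsets, and refits the winner on the full data. Ties are
#' broken toward fewer predictors, then lexicographic order of the
#' sorted predictor names.
#'
#' @param table data frame of subject features.
#' @param candidates nonempty character vector of candidate predictors.
#' @param response response column name.
#' @param k number of folds (default 10; must not exceed the number of
#'   subjects).
#' @param seed integer seed for the fold assignment.
#' @return A list with `best` (a [RegressionFit-class] refitted on all
#'   data, `cvMSE` filled in) and `ranking` (a data frame of all subsets
#'   with their CV MSE and adjusted \eqn{R^2}, sorted by CV MSE).
#' @examples
#' cohort <- makeCohort(rrmsCohortSpec(seed = 1))
#' sel <- exhaustiveCVSelect(cohort, c("m1", "m2", "lambda"), seed = 1)
#' sel$best
#' @export
exhaustiveCVSelect <- function(table, candidates,
                               response = "cortical_thickness", k = 10L,
                               seed = 1L) {
  if (length(candidates) == 0L)
    stop("'candidates' must be nonempty")
  n <- nrow(table)
  if (k > n)
    stop("'k' must not exceed the number of subjects")
  if (k < 2L)
    stop("'k' must be at least 2")
  y <- as.numeric(table[[response]])
  fold <- withSeed(seed, sample(rep_len(seq_len(k), n)))
  subsets <- allSubsets(candidates)
  Xfull <- designMatrix(table, candidates)
  mses <- vapply(subsets, function(s) {
    X <- Xfull[, c("(Intercept)", s), drop = FALSE]
    cvMSEForSubset(X, y, fold, k)
  }, numeric(1))
  sizes <- lengths(subsets)
  keys <- vapply(subsets, function(s) paste(sort(s), collapse = ","),
                 character(1))
  ord <- order(mses, sizes, keys)
  best <- subsets[[ord[1]]]
  fit <- fitOLS(table, best, response)
  fit@cvMSE <- mses[ord[1]]
  ranking <- data.frame(
    subset = keys,
    size = sizes,
    cvMSE = mses,
    adjR2 = vapply(subsets, function(s) fitOLS(table, s, response)@adjR2,
                   numeric(1)),
    stringsAsFactors = FALSE)[ord, ]
  rownames(ranking) <- NULL
  list(best = fit, ranking = ranking)
}

#' LMG relative importance decomposition of R-squared
#'
#' Decomposes the full model's \eqn{R^2} into per-predictor shares by
#' averaging, over all orderings of the predictors, the increase in
#' \eqn{R^2} when each predictor enters the model. Computed over subsets
#' with the standard ordering weights
#' \eqn{|S|!\,(p-|S|-1)!/p!}, which is exact and feasible for
#' \eqn{p \le 10}. Shares are nonnegative for full-rank designs in the
#' averaging sense and sum to the full-model \eqn{R^2}; `relative`
#' rescales them to sum to 1.
#'
#' @param table data frame of subject features.
#' @param predictors character vector, at most 10 predictors.
#' @param response response column name.
#' @return A data frame with columns `predictor`, `share` and
#'   `relative`, plus attribute `"r2"` (the full-model \eqn{R^2}).
#' @export
lmgImportance <- function(table, predictors,
                          response = "cortical_thickness") {
  p <- length(predictors)
  if (p < 1L) stop("'predictors' must be nonempty")
  if (p > 10L) stop("LMG averaging over subsets is limited to 10 predictors")
  y <- as.numeric(table[[response]])
  tss <- sum((y - mean(y))^2)
  Xfull <- designMatrix(table, predictors)
  r2Of <- function(s) {
    X <- Xfull[, c("(Intercept)", s), drop = FALSE]
    1 - sum(lm.fit(X, y)$residuals^2) / tss
  }
  subsets <- allSubsets(predictors)
  r2 <- vapply(subsets, r2Of, numeric(1))
  names(r2) <- vapply(subsets, function(s) paste(sort(s), collapse = ","),
                      character(1))
  lf <- lfactorial(0:p)
  shares <- vapply(predictors, function(j) {
    tot <- 0
    for (i in seq_along(subsets)) {
      s <- subsets[[i]]
      if (j %in% s) next
      w <- exp(lf[length(s) + 1] + lf[p - length(s)] - lf[p + 1])
      key <- paste(sort(c(s, j)), collapse = ",")
      tot <- tot + w * (r2[[key]] - r2[[i]])
    }
    tot
  }, numeric(1))
  out <- data.frame(predictor = predictors, share = unname(shares),
                    relative = unname(shares) / sum(shares),
                    stringsAsFactors = FALSE)
  attr(out, "r2") <- unname(r2[[length(subsets)]])
  out
}

#' Welch two-sample t-test
#'
#' Two-sided t-test with unequal variances and Welch--Satterthwaite
#' degrees of freedom, as used for all group comparisons.
#'
#' @param a,b numeric vectors, each of length at least 2; at least one
#'   must have positive variance.
#' @return A list with `t`, `df` and the two-sided `p`.
#' @examples
#' welchT(c(1, 2, 3), c(1, 2, 3, 4, 5))
#' @export
welchT <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values")
  if (var(a) == 0 && var(b) == 0)
    stop("degenerate samples: both have zero variance")
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Predictor change associated with a cortical-thickness change
#'
#' Interprets a regression coefficient all-else-equal: the predictor
#' change associated with a cortical thickness change of
#' `deltaThickness` mm is \eqn{\Delta / |\beta|}. The value is returned
#' at full precision; round only for presentation (the conventional
#' display uses 2 significant figures).
#'
#' @param model a [RegressionFit-class].
#' @param predictor name of a predictor in the model.
#' @param deltaThickness thickness change, mm (default 0.05).
#' @return The associated predictor change, in predictor units.
#' @export
deltaForThicknessChange <- function(model, predictor,
                                    deltaThickness = 0.05) {
  stopifnot(is(model, "RegressionFit"))
  if (!predictor %in% model@predictors)
    stop("'", predictor, "' is not a predictor of this model")
  beta <- model@coefficients[[predictor]]
  if (beta == 0)
    stop("coefficient for '", predictor,
         "' is zero: the associated change is undefined")
  deltaThickness / abs(beta)
}

#' Compare the gamma-mixture and lesion-mask predictor sets
#'
#' Runs the exhaustive cross-validated model search once per candidate
#' set -- the gamma-mixture reduction \eqn{(m_1, m_2, \lambda)} plus
#' covariates versus the lesion-mask means plus covariates -- and
#' reports both final models with their adjusted \eqn{R^2} and which set
#' explains more variance. The same seeded folds are used for both sets.
#'
#' @param table data frame of subject features.
#' @param setGamma,setMask the two candidate predictor sets.
#' @param response response column name.
#' @param k CV folds.
#' @param seed integer seed for the fold assignment.
#' @return A list with `gamma`, `mask` (each the result of
#'   [exhaustiveCVSelect()]) and `better` (`"gamma"`, `"mask"` or
#'   `"tie"` by adjusted \eqn{R^2} of the selected models).
#' @export
comparePredictorSets <- function(table,
                                 setGamma = c("m1", "m2", "lambda", "age",
                                              "gender", "dd", "dmt"),
                                 setMask = c("mean_lesion_mwf",
                                             "mean_nawm_mwf", "age",
                                             "gender", "dd", "dmt"),
                                 response = "cortical_thickness",
                                 k = 10L, seed = 1L) {
  gsel <- exhaustiveCVSelect(table, setGamma, response, k, seed)
  msel <- exhaustiveCVSelect(table, setMask, response, k, seed)
  ga <- gsel$best@adjR2
  ma <- msel$best@adjR2
  list(gamma = gsel, mask = msel,
       better = if (ga > ma) "gamma" else if (ma > ga) "mask" else "tie")
}
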