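# Internal helpers.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. With seed = NULL the expression uses the ambient RNG stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Moment-matched gamma (shape, scale) for an initialization split.
momentGamma <- function(v) {
  m <- mean(v)
  s2 <- var(v)
  if (!is.finite(s2) || s2 <= 0)
    stop("degenerate data: zero variance within an initialization split")
  c(shape = m^2 / s2, scale = s2 / m)
}

# MWF is a nonnegative ratio: negative values are a domain error, while
# exact zeros (mask artifacts) fall outside the gamma support and are
# excluded with their count recorded.
dropNonPositive <- function(values) {
  if (!is.numeric(values))
    stop("'values' must be numeric")
  values <- values[!is.na(values)]
  if (any(values < 0))
    stop("negative values are outside the gamma support (MWF is a ",
         "nonnegative ratio)")
  keep <- values > 0
  list(values = values[keep], nDropped = sum(!keep))
}
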