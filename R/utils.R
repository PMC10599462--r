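# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs the code as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Small-sample corrected AIC for least-squares fits with Gaussian errors.
# npar counts mean-model parameters; the error variance adds one.
aicc <- function(ss, n, npar) {
  k <- npar + 1
  if (n - k - 1 <= 0) return(Inf)
  ss <- max(ss, .Machine$double.xmin)
  n * log(ss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Weighted simple linear regression via closed-form normal equations.
# Weights are relative inverse variances; SEs use the weighted residual MSE.
wls_line <- function(x, y, w = rep(1, length(x))) {
  n <- length(x)
  stopifnot(length(y) == n, length(w) == n, n >= 2)
  W <- sum(w)
  xb <- sum(w * x) / W
  yb <- sum(w * y) / W
  sxx <- sum(w * (x - xb)^2)
  if (sxx <= 0) stop("degenerate abscissae: all x identical")
  slope <- sum(w * (x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  resid <- y - intercept - slope * x
  ss <- sum(w * resid^2)
  df <- n - 2
  s2 <- if (df > 0) ss / df else NA_real_
  list(
    slope = slope, intercept = intercept,
    slope_se = if (df > 0) sqrt(s2 / sxx) else NA_real_,
    intercept_se = if (df > 0) sqrt(s2 * (1 / W + xb^2 / sxx)) else NA_real_,
    ss = ss, n = n, df = df,
    x = x, y = y, w = w, resid = resid
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_arg <- function(...) stop(..., call. = FALSE)
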