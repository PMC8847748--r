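#' @keywords internal
#' @import stats
#' @importFrom utils read.csv write.csv str
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Mean of a normal N(mu, sigma^2) censored (clipped) to [lo, hi], closed form.
censored_normal_mean <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  lo * pnorm(a) + hi * (1 - pnorm(b)) +
    mu * (pnorm(b) - pnorm(a)) + sigma * (dnorm(a) - dnorm(b))
}

# Location mu* such that clipping N(mu*, sigma^2) to [lo, hi] has mean `target`.
calibrate_clip_location <- function(target, sigma, lo, hi) {
  if (!is.finite(lo) && !is.finite(hi)) return(target)
  f <- function(mu) censored_normal_mean(mu, sigma, lo, hi) - target
  lo_f <- if (is.finite(lo)) lo else target - 10 * sigma
  hi_f <- if (is.finite(hi)) hi else target + 10 * sigma
  uniroot(f, lower = lo_f - 10 * sigma, upper = hi_f + 10 * sigma,
          tol = 1e-10)$root
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
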