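# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not disturb the
#' caller's RNG stream. A `NULL` seed evaluates the expression as-is.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage / per-subject sub-seed from a global seed
#'
#' Deterministic mixing kept below 2^31 so results fit in an R integer.
#'
#' @param seed Global integer seed.
#' @param offset Non-negative integer offset (stage or subject index).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + as.double(offset) * 9973 + 12345) %%
    2147483647)
}

#' Draw from a normal distribution truncated below
#'
#' Rejection sampling; adequate for the mild truncations used here (the
#' capacity floor 0.3 bps is ~5 SD below the configured group means).
#'
#' @param n Number of draws.
#' @param mean,sd Normal parameters.
#' @param lower Lower truncation bound.
#' @return Numeric vector of length `n`.
#' @export
rtnorm_lower <- function(n, mean, sd, lower) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
  }
  out
}

#' Draw ex-Gaussian reaction times
#'
#' Sum of a normal and an exponential component, the standard RT model.
#' The mean of the distribution is `mu + tau`.
#'
#' @param n Number of draws.
#' @param mu,sigma Normal component parameters (ms).
#' @param tau Exponential component mean (ms); 0 gives a pure normal.
#' @return Numeric vector of RTs in ms.
#' @keywords internal
rexgauss <- function(n, mu, sigma, tau) {
  rt <- stats::rnorm(n, mu, sigma)
  if (tau > 0) rt <- rt + stats::rexp(n, rate = 1 / tau)
  rt
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Stop with a configuration error naming the offending field
#' @keywords internal
stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
    call. = FALSE
  )
}
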