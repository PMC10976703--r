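#' Truncated normal sampling and moments
#'
#' Inverse-CDF sampler and first moment of the normal distribution
#' truncated to `[lower, upper]`. Used for conversion intervals,
#' follow-up durations and any bounded positive quantity drawn by the
#' cohort generator.
#'
#' @param n Number of draws.
#' @param mean,sd Location and scale of the parent normal; `sd > 0`.
#' @param lower,upper Truncation bounds (may be infinite).
#' @return `rtruncnorm()`: numeric vector of `n` draws in
#'   `[lower, upper]`. `truncnorm_mean()`: the exact mean of the
#'   truncated distribution.
#' @examples
#' x <- rtruncnorm(5, 3.7, 1.68, lower = 1, upper = 8)
#' truncnorm_mean(3.7, 1.68, lower = 1, upper = 8)
#' @export
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  stopifnot(sd > 0, lower < upper, n >= 0)
  if (n == 0) return(numeric(0))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  if (phi - plo < .Machine$double.eps) {
    stop("truncation interval [", lower, ", ", upper,
         "] has negligible probability under Normal(", mean, ", ", sd, ")")
  }
  u <- runif(n, plo, phi)
  pmin(pmax(qnorm(u, mean, sd), lower), upper)
}

#' @rdname rtruncnorm
#' @export
truncnorm_mean <- function(mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  stopifnot(sd > 0, lower < upper)
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- pnorm(b) - pnorm(a)
  mean + sd * (dnorm(a) - dnorm(b)) / z
}
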