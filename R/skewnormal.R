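# Azzalini skew-normal: density, sampling, moments.
# Parameterization: location xi, scale omega > 0, shape alpha;
# delta = alpha / sqrt(1 + alpha^2); mean = xi + omega * delta * sqrt(2/pi).

#' Skew-normal density
#'
#' @param x quantiles.
#' @param xi location.
#' @param omega scale (> 0).
#' @param alpha shape (0 gives the normal density).
#' @param log return log density?
#' @return density values.
#' @export
dskewnorm <- function(x, xi = 0, omega = 1, alpha = 0, log = FALSE) {
  if (omega <= 0) stopf("'omega' must be > 0")
  z <- (x - xi) / omega
  ld <- log(2) - log(omega) + stats::dnorm(z, log = TRUE) +
    stats::pnorm(alpha * z, log.p = TRUE)
  if (log) ld else exp(ld)
}

#' Skew-normal random draws
#'
#' Uses the convolution representation
#' `X = xi + omega * (delta * |U| + sqrt(1 - delta^2) * V)` with independent
#' standard normals U, V.
#'
#' @param n number of draws.
#' @inheritParams dskewnorm
#' @return numeric vector.
#' @export
rskewnorm <- function(n, xi = 0, omega = 1, alpha = 0) {
  if (any(omega <= 0)) stopf("'omega' must be > 0")
  delta <- alpha / sqrt(1 + alpha^2)
  u <- abs(stats::rnorm(n))
  v <- stats::rnorm(n)
  xi + omega * (delta * u + sqrt(1 - delta^2) * v)
}

#' Skew-normal moments
#'
#' Mean `xi + omega * delta * sqrt(2/pi)` and standard deviation
#' `omega * sqrt(1 - 2 delta^2 / pi)`.
#'
#' @inheritParams dskewnorm
#' @return named list with `mean` and `sd`.
#' @export
skewnorm_moments <- function(xi = 0, omega = 1, alpha = 0) {
  delta <- alpha / sqrt(1 + alpha^2)
  list(mean = xi + omega * delta * sqrt(2 / pi),
       sd = omega * sqrt(1 - 2 * delta^2 / pi))
}
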