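#' The Inverse Gaussian (Wald) Distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the inverse Gaussian distribution with mean `mu` and shape `lambda`,
#' the dwell-time family used by all benchmark generators in this package.
#'
#' The density is
#' \deqn{f(t) = \sqrt{\lambda / (2\pi t^3)}\,
#'   \exp\{-\lambda (t - \mu)^2 / (2 \mu^2 t)\}, \quad t > 0.}
#' The mean is \eqn{\mu} and the variance \eqn{\mu^3/\lambda}.
#'
#' @param t,q vector of (positive) quantiles.
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param mu mean parameter, `> 0`.
#' @param lambda shape parameter, `> 0`.
#' @param log,log.p logical; if `TRUE`, densities/probabilities are returned
#'   on the log scale.
#' @return `dinvgauss` gives the density, `pinvgauss` the CDF, `qinvgauss`
#'   the quantile function and `rinvgauss` random draws.
#' @examples
#' integrate(dinvgauss, 0, Inf, mu = 1, lambda = 5)
#' pinvgauss(qinvgauss(0.9, 3, 2), 3, 2)
#' @name invgauss
NULL

#' @rdname invgauss
#' @export
dinvgauss <- function(t, mu, lambda, log = FALSE) {
  stopifnot(mu > 0, lambda > 0)
  out <- rep(-Inf, length(t))
  ok <- is.finite(t) & t > 0
  tt <- t[ok]
  out[ok] <- 0.5 * (log(lambda) - log(2 * pi) - 3 * log(tt)) -
    lambda * (tt - mu)^2 / (2 * mu^2 * tt)
  if (log) out else exp(out)
}

#' @rdname invgauss
#' @export
pinvgauss <- function(q, mu, lambda, log.p = FALSE) {
  stopifnot(mu > 0, lambda > 0)
  out <- numeric(length(q))
  ok <- is.finite(q) & q > 0
  qq <- q[ok]
  a <- sqrt(lambda / qq)
  # standard closed form in terms of the normal CDF
  out[ok] <- pnorm(a * (qq / mu - 1)) +
    exp(2 * lambda / mu + pnorm(-a * (qq / mu + 1), log.p = TRUE))
  out[is.finite(q) & q <= 0] <- 0
  out[q == Inf] <- 1
  out <- pmin(pmax(out, 0), 1)
  if (log.p) log(out) else out
}

#' @rdname invgauss
#' @export
qinvgauss <- function(p, mu, lambda) {
  stopifnot(mu > 0, lambda > 0, all(p >= 0 & p <= 1))
  vapply(p, function(pp) {
    if (pp <= 0) return(0)
    if (pp >= 1) return(Inf)
    f <- function(q) pinvgauss(q, mu, lambda) - pp
    # bracket: mean +/- enough sds on the log scale
    lo <- mu * 1e-8
    hi <- mu + 20 * sqrt(mu^3 / lambda)
    while (f(hi) < 0) hi <- hi * 2
    uniroot(f, c(lo, hi), tol = 1e-12)$root
  }, numeric(1))
}

#' @rdname invgauss
#' @export
rinvgauss <- function(n, mu, lambda) {
  stopifnot(mu > 0, lambda > 0)
  # Michael, Schucany & Haas (1976) transformation with a uniform choice
  # between the two roots
  nu <- rnorm(n)
  y <- nu^2
  x <- mu + mu^2 * y / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
  u <- runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}
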