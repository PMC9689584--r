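#' Dwell-time models
#'
#' A `dwell_model` is a probability density on the positive half-line used
#' for the time a hidden state keeps emitting its symbol before the next
#' symbol change.  Supported kinds: parametric inverse Gaussian
#' (`dwell_invgauss`), finite mixtures of inverse Gaussians
#' (`dwell_mixture`), exponential (`dwell_exponential`, the memoryless
#' baseline), uniform (`dwell_uniform`), Gaussian-kernel (Parzen)
#' estimates (`dwell_kernel`), k-nearest-neighbor estimates (`dwell_knn`)
#' and the neural estimator returned by [fit_neural_density()].  All kinds
#' answer the generics [ddwell()], [rdwell()], [dwell_mean()] and
#' [dwell_support()].
#'
#' @param mu,lambda inverse-Gaussian mean and shape, both `> 0`.
#' @param rate exponential rate, `> 0`.
#' @param lo,hi uniform bounds, `0 <= lo < hi`.
#' @param weights mixture weights (nonnegative, will be normalized).
#' @param components list of `dwell_invgauss` components.
#' @param samples numeric vector of observed dwell times.
#' @param bandwidth Gaussian kernel bandwidth `h > 0`.
#' @param k neighbor count, `1 <= k < length(samples)`.
#' @return an object of class `dwell_model`.
#' @examples
#' m <- dwell_invgauss(1, 5)
#' dwell_mean(m)
#' integrate(function(t) ddwell(m, t), 0, Inf)
#' @name dwell_model
NULL

new_dwell <- function(kind, fields) {
  structure(c(list(kind = kind), fields),
            class = c(paste0("dwell_", kind), "dwell_model"))
}

#' @rdname dwell_model
#' @export
dwell_invgauss <- function(mu, lambda) {
  stopifnot(is.numeric(mu), is.numeric(lambda), mu > 0, lambda > 0)
  new_dwell("invgauss", list(mu = mu, lambda = lambda))
}

#' @rdname dwell_model
#' @export
dwell_mixture <- function(weights, components) {
  stopifnot(length(weights) == length(components), all(weights >= 0),
            sum(weights) > 0)
  ok <- vapply(components, inherits, logical(1), "dwell_invgauss")
  if (!all(ok)) stop("mixture components must be inverse-Gaussian dwell models")
  new_dwell("mixture",
            list(weights = weights / sum(weights), components = components))
}

#' @rdname dwell_model
#' @export
dwell_exponential <- function(rate) {
  stopifnot(is.numeric(rate), rate > 0)
  new_dwell("exponential", list(rate = rate))
}

#' @rdname dwell_model
#' @export
dwell_uniform <- function(lo, hi) {
  stopifnot(is.numeric(lo), is.numeric(hi), lo >= 0, hi > lo)
  new_dwell("uniform", list(lo = lo, hi = hi))
}

#' @rdname dwell_model
#' @export
dwell_kernel <- function(samples, bandwidth) {
  stopifnot(length(samples) >= 1, all(samples > 0), bandwidth > 0)
  new_dwell("kernel", list(samples = as.numeric(samples), h = bandwidth))
}

#' @rdname dwell_model
#' @export
dwell_knn <- function(samples, k) {
  samples <- as.numeric(samples)
  stopifnot(length(samples) >= 2, all(samples > 0))
  k <- as.integer(k)
  if (k < 1L || k >= length(samples)) stop("need 1 <= k < number of samples")
  new_dwell("knn", list(samples = samples, k = k))
}

#' Evaluate, sample, and summarize dwell-time models
#'
#' `ddwell` evaluates the density at `t`; `rdwell` draws `n` samples using
#' the current RNG state; `dwell_mean` returns the mean dwell
#' \eqn{\mu = \int t\,\phi(t)\,dt}; `dwell_support` returns the interval
#' outside which the density is (numerically) zero, used to set quadrature
#' ranges.
#'
#' @param model a [dwell_model] object.
#' @param t numeric vector of evaluation points.
#' @param n number of draws.
#' @param ... passed to methods.
#' @return `ddwell`: numeric vector of densities; `rdwell`: numeric vector
#'   of draws; `dwell_mean`: scalar; `dwell_support`: length-2 numeric.
#' @export
ddwell <- function(model, t, ...) UseMethod("ddwell")

#' @rdname ddwell
#' @export
rdwell <- function(model, n, ...) UseMethod("rdwell")

#' @rdname ddwell
#' @export
dwell_mean <- function(model, ...) UseMethod("dwell_mean")

#' @rdname ddwell
#' @export
dwell_support <- function(model, ...) UseMethod("dwell_support")

## --- inverse Gaussian -----------------------------------------------------

#' @export
ddwell.dwell_invgauss <- function(model, t, ...)
  dinvgauss(t, model$mu, model$lambda)

#' @export
rdwell.dwell_invgauss <- function(model, n, ...)
  rinvgauss(n, model$mu, model$lambda)

#' @export
dwell_mean.dwell_invgauss <- function(model, ...) model$mu

#' @export
dwell_support.dwell_invgauss <- function(model, tail = 1e-8, ...)
  c(1e-6, qinvgauss(1 - tail, model$mu, model$lambda))

## --- mixture --------------------------------------------------------------

#' @export
ddwell.dwell_mixture <- function(model, t, ...) {
  out <- 0
  for (i in seq_along(model$weights))
    out <- out + model$weights[i] * ddwell(model$components[[i]], t)
  out
}

#' @export
rdwell.dwell_mixture <- function(model, n, ...) {
  idx <- sample.int(length(model$weights), n, replace = TRUE,
                    prob = model$weights)
  out <- numeric(n)
  for (i in seq_along(model$weights)) {
    sel <- idx == i
    if (any(sel)) out[sel] <- rdwell(model$components[[i]], sum(sel))
  }
  out
}

#' @export
dwell_mean.dwell_mixture <- function(model, ...)
  sum(model$weights * vapply(model$components, dwell_mean, numeric(1)))

#' @export
dwell_support.dwell_mixture <- function(model, ...) {
  sup <- vapply(model$components, dwell_support, numeric(2))
  c(min(sup[1, ]), max(sup[2, ]))
}

## --- exponential (Poisson-clock baseline) ---------------------------------

#' @export
ddwell.dwell_exponential <- function(model, t, ...)
  stats::dexp(t, rate = model$rate)

#' @export
rdwell.dwell_exponential <- function(model, n, ...)
  stats::rexp(n, rate = model$rate)

#' @export
dwell_mean.dwell_exponential <- function(model, ...) 1 / model$rate

#' @export
dwell_support.dwell_exponential <- function(model, tail = 1e-8, ...)
  c(1e-6, stats::qexp(1 - tail, rate = model$rate))

## --- uniform ---------------------------------------------------------------

#' @export
ddwell.dwell_uniform <- function(model, t, ...)
  stats::dunif(t, model$lo, model$hi)

#' @export
rdwell.dwell_uniform <- function(model, n, ...)
  stats::runif(n, model$lo, model$hi)

#' @export
dwell_mean.dwell_uniform <- function(model, ...) (model$lo + model$hi) / 2

#' @export
dwell_support.dwell_uniform <- function(model, ...) c(model$lo, model$hi)

## --- Gaussian kernel (Parzen) --------------------------------------------

#' @export
ddwell.dwell_kernel <- function(model, t, ...) {
  vapply(t, function(tt) mean(dnorm(tt, mean = model$samples, sd = model$h)),
         numeric(1))
}

#' @export
rdwell.dwell_kernel <- function(model, n, ...)
  sample(model$samples, n, replace = TRUE) + rnorm(n, sd = model$h)

#' @export
dwell_mean.dwell_kernel <- function(model, ...) mean(model$samples)

#' @export
dwell_support.dwell_kernel <- function(model, ...)
  c(min(model$samples) - 8 * model$h, max(model$samples) + 8 * model$h)

## --- k-nearest neighbor ---------------------------------------------------

#' @export
ddwell.dwell_knn <- function(model, t, ...) {
  # phi(t) = k / (2 n r_k(t)); exact-zero distances are excluded so the
  # estimate stays finite at sample points
  r <- kth_dist_1d(as.numeric(t), model$samples, model$k, TRUE)
  model$k / (2 * length(model$samples) * r)
}

#' @export
rdwell.dwell_knn <- function(model, n, ...)
  sample(model$samples, n, replace = TRUE)

#' @export
dwell_mean.dwell_knn <- function(model, ...) mean(model$samples)

#' @export
dwell_support.dwell_knn <- function(model, ...)
  range(model$samples)

#' @export
print.dwell_model <- function(x, ...) {
  cat("<dwell_model:", x$kind, "> mean", format(dwell_mean(x), digits = 4),
      "\n")
  invisible(x)
}

# trapezoidal rule on an arbitrary sorted grid
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# differential entropy -int phi log phi of a dwell model by adaptive
# quadrature on its support
dwell_entropy <- function(model, rel.tol = 1e-9) {
  sup <- dwell_support(model)
  f <- function(t) {
    p <- ddwell(model, t)
    ifelse(p > 0, -p * log(p), 0)
  }
  stats::integrate(f, max(sup[1], 1e-12), sup[2], rel.tol = rel.tol,
                   subdivisions = 500L)$value
}

# mean dwell by quadrature (for estimators defined via numeric integration)
dwell_mean_numeric <- function(model, rel.tol = 1e-9) {
  sup <- dwell_support(model)
  stats::integrate(function(t) t * ddwell(model, t),
                   max(sup[1], 1e-12), sup[2], rel.tol = rel.tol,
                   subdivisions = 500L)$value
}
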