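#' Configuration for the neural dwell-density estimator
#'
#' Architecture and training settings for [fit_neural_density()].  The
#' default is the five-layer, 15-node network trained for 3000 Adam epochs
#' used by the package's reference experiments; the scaled-down validation
#' experiments shrink these (see the methods vignette for the sizes used
#' and why).
#'
#' @param layers total layer count including input and output (so
#'   `layers - 2` hidden layers; the last hidden layer uses ReLU
#'   activations, earlier ones tanh).
#' @param width hidden-layer width, `>= 1`.
#' @param epochs full-batch Adam epochs, `>= 1`.
#' @param learning_rate Adam step size.  If training diverges the fit is
#'   automatically retried at a tenth of the rate.
#' @param seeds integer vector of initialization seeds; the fit with the
#'   best held-out log-likelihood is returned.
#' @param integration_grid number of trapezoid points used for the
#'   in-training normalization integral.
#' @param holdout_frac fraction of samples held out for seed selection.
#' @return a list of class `density_fit_config`.
#' @export
density_fit_config <- function(layers = 5L, width = 15L, epochs = 3000L,
                               learning_rate = 1e-3, seeds = 1:5,
                               integration_grid = 1024L,
                               holdout_frac = 0.2) {
  stopifnot(layers >= 3, width >= 1, epochs >= 1, learning_rate > 0,
            length(seeds) >= 1, integration_grid >= 8,
            holdout_frac >= 0, holdout_frac < 1)
  structure(list(layers = as.integer(layers), width = as.integer(width),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 seeds = as.integer(seeds),
                 integration_grid = as.integer(integration_grid),
                 holdout_frac = holdout_frac),
            class = "density_fit_config")
}

# number of trainable parameters of a network with this configuration;
# enters the BIC penalty of model selection
nnet_param_count <- function(config) {
  w <- config$width
  nh <- config$layers - 2L
  (w + w) +                        # input weights + biases
    (nh - 1L) * (w * w + w) +      # hidden-to-hidden
    (w + 1L)                       # output weights u and bias c
}

nnet_init <- function(config) {
  w <- config$width
  nh <- config$layers - 2L
  W <- b <- vector("list", nh)
  W[[1]] <- rnorm(w, sd = 1)
  b[[1]] <- rnorm(w, sd = 0.5)
  if (nh > 1) for (l in 2:nh) {
    W[[l]] <- rnorm(w * w, sd = sqrt(2 / w))
    b[[l]] <- rep(0, w)
  }
  list(W = W, b = b, u = rnorm(w, sd = sqrt(1 / w)), c = 0.5)
}

# standardized log-dwell input; dwell scales differ widely across states
nnet_z <- function(t, log_mean, log_sd) (log(t) - log_mean) / log_sd

neural_density_raw <- function(params, t, log_mean, log_sd)
  nnet_raw(params, nnet_z(t, log_mean, log_sd))

#' Fit a dwell density with a normalized neural network
#'
#' Trains a small feedforward network mapping a dwell time to a
#' nonnegative raw output (ReLU penultimate activations; final-layer
#' weights squared so they cannot go negative) and defines the density as
#' the raw output divided by a trapezoidal integral of the raw output over
#' the sample range.  The density is identically zero outside
#' `[min(samples), max(samples)]`: the network interpolates well but is
#' not trusted to extrapolate.  Training minimizes the negative
#' log-likelihood of the samples under the normalized density with
#' full-batch Adam.  One fit is run per seed in `config$seeds` (each on an
#' 80/20 train/holdout split that is fixed across seeds) and the fit with
#' the highest held-out log-likelihood is returned, so model selection
#' never peeks at ground truth.
#'
#' @param samples positive dwell times; at least two distinct values.
#' @param config a [density_fit_config()].
#' @return a [dwell_model] of kind `neural`.  The returned density
#'   integrates to one over its support to within about `1e-3`.
#' @export
fit_neural_density <- function(samples, config = density_fit_config()) {
  samples <- as.numeric(samples)
  if (length(samples) < 2) stop("need at least 2 samples")
  if (any(!is.finite(samples)) || any(samples <= 0))
    stop("samples must be positive and finite")
  if (length(unique(samples)) < 2)
    stop("degenerate support: all samples are equal")
  support <- range(samples)
  log_mean <- mean(log(samples))
  log_sd <- max(stats::sd(log(samples)), 1e-8)

  n <- length(samples)
  n_hold <- floor(config$holdout_frac * n)
  # split fixed across seeds so seed selection compares like with like
  old <- .Random.seed_get()
  set.seed(config$seeds[1] + 104729L)
  hold_idx <- if (n_hold >= 1) sample.int(n, n_hold) else integer(0)
  train <- if (n_hold >= 1) samples[-hold_idx] else samples
  hold <- samples[hold_idx]
  if (length(unique(train)) < 2) { train <- samples; hold <- numeric(0) }

  grid <- seq(support[1], support[2], length.out = config$integration_grid)
  h <- grid[2] - grid[1]
  tw <- c(h / 2, rep(h, length(grid) - 2), h / 2)
  z_all <- nnet_z(c(train, grid), log_mean, log_sd)

  best <- NULL
  for (seed in config$seeds) {
    set.seed(seed)
    init <- nnet_init(config)
    lr <- config$learning_rate
    fit <- NULL
    for (attempt in 1:3) { # divergence -> retry at lr/10
      res <- nnet_train(init, z_all, length(train), tw, config$epochs, lr)
      if (isTRUE(res$ok) && is.finite(res$loss)) { fit <- res; break }
      lr <- lr / 10
    }
    if (is.null(fit)) next
    dens <- make_neural_dwell(fit$params, support, log_mean, log_sd)
    score <- if (length(hold)) {
      sum(log(pmax(ddwell(dens, hold), 1e-12)))
    } else {
      -fit$loss # no holdout: fall back to training likelihood
    }
    if (is.null(best) || score > best$score)
      best <- list(score = score, dens = dens, seed = seed)
  }
  .Random.seed_set(old)
  if (is.null(best))
    stop("neural density training diverged for every seed")
  best$dens$seed <- best$seed
  best$dens$holdout_ll <- best$score
  best$dens
}

# restore-on-exit helpers so fitting does not perturb the caller's RNG
.Random.seed_get <- function()
  if (exists(".Random.seed", envir = .GlobalEnv)) get(".Random.seed", envir = .GlobalEnv) else NULL
.Random.seed_set <- function(seed)
  if (!is.null(seed)) assign(".Random.seed", seed, envir = .GlobalEnv)

make_neural_dwell <- function(params, support, log_mean, log_sd,
                              norm_grid = 4096L) {
  g <- seq(support[1], support[2], length.out = norm_grid)
  raw <- neural_density_raw(params, g, log_mean, log_sd)
  nc <- trapz(g, raw)
  new_dwell("neural", list(params = params, support = support,
                           log_mean = log_mean, log_sd = log_sd,
                           norm_const = nc))
}

#' @export
ddwell.dwell_neural <- function(model, t, ...) {
  out <- numeric(length(t))
  ok <- t >= model$support[1] & t <= model$support[2]
  if (any(ok))
    out[ok] <- neural_density_raw(model$params, t[ok], model$log_mean,
                                  model$log_sd) / model$norm_const
  out
}

#' @export
rdwell.dwell_neural <- function(model, n, ...) {
  g <- seq(model$support[1], model$support[2], length.out = 2048L)
  d <- ddwell(model, g)
  cdf <- cumsum(c(0, (d[-1] + d[-length(d)]) / 2 * diff(g)))
  cdf <- cdf / cdf[length(cdf)]
  keep <- !duplicated(cdf)
  stats::approx(cdf[keep], g[keep], runif(n), rule = 2)$y
}

#' @export
dwell_mean.dwell_neural <- function(model, ...) {
  g <- seq(model$support[1], model$support[2], length.out = 4096L)
  trapz(g, g * ddwell(model, g))
}

#' @export
dwell_support.dwell_neural <- function(model, ...) model$support

#' Fit a dwell density with a Gaussian kernel (Parzen window)
#'
#' Selects the bandwidth `h` maximizing the leave-one-out pseudo-likelihood
#' \deqn{\sum_i \log \frac{1}{n-1} \sum_{j \ne i} K_h(\tau_i - \tau_j)}
#' over `bandwidth_grid` and returns the kernel density with that
#' bandwidth.  Deterministic given the samples and the grid; bandwidth
#' ties resolve to the smaller `h`.
#'
#' @param samples numeric vector of at least two positive dwell times.
#' @param bandwidth_grid candidate bandwidths; defaults to a log-spaced
#'   grid around Silverman's rule-of-thumb value.
#' @return a [dwell_model] of kind `kernel`.
#' @export
fit_kernel_density <- function(samples, bandwidth_grid = NULL) {
  samples <- as.numeric(samples)
  stopifnot(length(samples) >= 2)
  if (is.null(bandwidth_grid)) {
    sil <- 1.06 * stats::sd(samples) * length(samples)^(-1 / 5)
    if (!is.finite(sil) || sil <= 0) sil <- max(diff(range(samples)), 1e-3)
    bandwidth_grid <- sil * 2^seq(-4, 2, length.out = 15)
  }
  if (!length(bandwidth_grid) || any(bandwidth_grid <= 0))
    stop("bandwidth grid must be nonempty and positive")
  bandwidth_grid <- sort(bandwidth_grid)
  ll <- loo_pseudo_loglik(samples, bandwidth_grid)
  h <- bandwidth_grid[which.max(ll)]
  dwell_kernel(samples, h)
}

# leave-one-out pseudo-log-likelihood for each candidate bandwidth,
# computed blockwise to bound memory at large n
loo_pseudo_loglik <- function(x, hs, block = 1024L) {
  n <- length(x)
  ll <- numeric(length(hs))
  for (start in seq(1, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    D <- outer(x[idx], x, "-")
    self <- cbind(seq_along(idx), idx)
    for (j in seq_along(hs)) {
      K <- dnorm(D, sd = hs[j])
      # zero the self term rather than subtracting it afterwards: for an
      # isolated point the neighbor mass is far below the self kernel and
      # the subtraction would cancel catastrophically
      K[self] <- 0
      s <- rowSums(K)
      ll[j] <- ll[j] + sum(log(pmax(s / (n - 1), 1e-300)))
    }
  }
  ll
}

#' Fit a dwell density by k-nearest-neighbor distances
#'
#' The estimate is \eqn{\hat\phi(t) = k / (2 n r_k(t))} with \eqn{r_k(t)}
#' the distance from `t` to its k-th nearest sample (exact-zero distances
#' excluded, so the estimate is finite at the sample points themselves).
#' `k = "auto"` uses \eqn{k = \lceil \sqrt n \rceil} rounded, a standard
#' consistency-guided choice.
#'
#' @param samples numeric vector of positive dwell times.
#' @param k neighbor count with `1 <= k < length(samples)`, or `"auto"`.
#' @return a [dwell_model] of kind `knn`.  Note the estimate's tails decay
#'   like `1/t`, so it is not integrable over the whole half-line; it is a
#'   pointwise estimate, scored on finite grids.
#' @export
fit_knn_density <- function(samples, k = "auto") {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (identical(k, "auto")) k <- max(1L, as.integer(round(sqrt(n))))
  k <- as.integer(k)
  if (k >= n || k < 1) stop("need 1 <= k < number of samples")
  dwell_knn(samples, k)
}

#' Integrated squared error between two densities
#'
#' Trapezoidal integral of the squared difference of two dwell densities
#' over a grid; the figure of merit used to compare density estimators
#' against a known ground truth.
#'
#' @param estimate,truth [dwell_model] objects.
#' @param grid sorted numeric evaluation grid.
#' @return nonnegative scalar.
#' @export
mise <- function(estimate, truth, grid) {
  grid <- as.numeric(grid)
  if (!length(grid)) stop("grid must be nonempty")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be sorted, increasing")
  d <- ddwell(estimate, grid) - ddwell(truth, grid)
  trapz(grid, d^2)
}
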