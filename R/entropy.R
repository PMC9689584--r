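#' Model-based plug-in differential entropy rate
#'
#' Re-estimates each state's dwell density from the decoded per-state
#' dwell samples of a fit with a Parzen-window (Gaussian kernel) estimate
#' whose bandwidth maximizes the leave-one-out pseudo-likelihood, then
#' evaluates the plug-in entropy-rate formula
#' \deqn{\hat h_\mu = -\sum_s \hat p(s) \int_0^\infty \hat\mu_s
#'   \hat\phi_s(t) \log \hat\phi_s(t)\, dt,}
#' with \eqn{\hat\mu_s = \int t \hat\phi_s(t) dt} computed numerically and
#' \eqn{\hat p(s)} solved from the decoded transition counts via
#' [stationary_distribution()].  Kernel estimates are the default here
#' (rather than the neural fits used for model selection) because they
#' carry lower mean-squared error once the topology is pinned down.
#'
#' @param fit a `ctbsi_fit` from [fit_topology()].
#' @param bandwidth_grid optional bandwidth grid for
#'   [fit_kernel_density()].
#' @param dwell_models optional named list of [dwell_model]s, one per
#'   state, substituted for the kernel re-estimates (benchmark mode: pass
#'   the generator's exact densities to recover the exact rate).
#' @return entropy-rate estimate in nats.
#' @export
plugin_entropy_rate <- function(fit, bandwidth_grid = NULL,
                                dwell_models = NULL) {
  stopifnot(inherits(fit, "ctbsi_fit"))
  states <- fit$model$topology$states
  if (is.null(dwell_models)) {
    for (s in states)
      if (length(fit$dwell_samples[[s]]) < 2)
        stop(sprintf("state %s has fewer than 2 dwell samples", s))
    kinds <- vapply(fit$model$dwell[states], function(d) d$kind, character(1))
    if (all(kinds == "kernel") && is.null(bandwidth_grid)) {
      # the fit already holds pseudo-likelihood Parzen estimates of the
      # same per-state samples; refitting would reproduce them
      dwell_models <- fit$model$dwell[states]
    } else {
      dwell_models <- lapply(fit$dwell_samples[states], fit_kernel_density,
                             bandwidth_grid = bandwidth_grid)
    }
  } else {
    dwell_models <- dwell_models[states]
  }
  mu <- vapply(dwell_models, dwell_mean_numeric, numeric(1))
  trans <- path_transition_counts(fit$state_path, states)
  p <- stationary_distribution(stats::setNames(mu, states), trans)
  H <- vapply(dwell_models, dwell_entropy, numeric(1))
  sum(p * mu * H)
}

path_transition_counts <- function(path, states) {
  n <- length(path)
  trans <- matrix(0, length(states), length(states),
                  dimnames = list(states, states))
  if (n >= 2) {
    t2 <- table(factor(path[-n], levels = states),
                factor(path[-1], levels = states))
    trans <- trans + unclass(t2)
  }
  trans
}

#' Kozachenko-Leonenko k-nearest-neighbor differential entropy
#'
#' Nonparametric estimate of the differential entropy (nats) of a sample
#' of d-dimensional points:
#' \deqn{\hat H = \psi(n) - \psi(k) + \log c_d +
#'   \frac{d}{n} \sum_i \log r_{k,i},}
#' with \eqn{c_d} the volume of the d-dimensional unit ball and
#' \eqn{r_{k,i}} the Euclidean distance from point `i` to its k-th nearest
#' neighbor.  Duplicate points (zero neighbor distances) are jittered at
#' `1e-12` scale with a warning so the estimate stays finite.
#'
#' @param points numeric matrix (rows = points) or vector (treated as 1-d).
#' @param k neighbor order, `1 <= k < n`; `k = 3` is the package-wide
#'   default.
#' @return entropy estimate in nats.
#' @examples
#' set.seed(1)
#' kl_knn_entropy(rnorm(5000))  # ~ 0.5 * log(2 * pi * exp(1)) = 1.419
#' @export
kl_knn_entropy <- function(points, k = 3L) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points); d <- ncol(points)
  if (n <= k) stop("need more points than k")
  r <- kth_nn_dist(points, as.integer(k))
  if (any(r == 0)) {
    warning("duplicate points; applying 1e-12-scale jitter")
    points <- points + matrix(stats::rnorm(n * d, sd = 1e-12), n, d)
    r <- kth_nn_dist(points, as.integer(k))
  }
  log_cd <- (d / 2) * log(pi) - lgamma(d / 2 + 1)
  digamma(n) - digamma(k) + log_cd + (d / n) * sum(log(r))
}

#' Trajectory ensembles
#'
#' A collection of independent event sequences all observed over the same
#' time window `[0, T]` (final dwell censored at `T`), the raw material of
#' the model-free entropy estimator.
#'
#' @param sequences list of [event_seq] objects, each of total duration
#'   `T` with a censored final dwell.
#' @param T the common observation window.
#' @return an object of class `trajectory_ensemble`.
#' @seealso [simulate_ensemble()] to build one from a model.
#' @export
trajectory_ensemble <- function(sequences, T) {
  stopifnot(length(sequences) >= 1, T > 0)
  dur <- vapply(sequences, function(s) sum(s$dwell), numeric(1))
  if (any(abs(dur - T) > 1e-8 * max(1, T)))
    stop("every trajectory must have total duration T")
  structure(list(sequences = sequences, T = T),
            class = "trajectory_ensemble")
}

#' Simulate an ensemble of fixed-duration trajectories
#'
#' @param model a valid [uhsmm].
#' @param n_traj number of independent trajectories.
#' @param T observation window per trajectory.
#' @param seed optional integer seed.
#' @return a [trajectory_ensemble()].
#' @export
simulate_ensemble <- function(model, n_traj, T, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sims <- lapply(seq_len(n_traj), function(i)
    simulate(model, duration = T)$sequence)
  trajectory_ensemble(sims, T)
}

plugin_discrete_entropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log(p))
}

#' Entropy of a trajectory ensemble
#'
#' Estimates the joint entropy \eqn{H[(x, \tau)_{0:T}]} of the windowed
#' process by conditioning on the event count and splitting discrete from
#' continuous components:
#' \deqn{H = \hat H[N] + \hat H[x_{0:n} | N] +
#'   \hat H[\tau_{0:n} | x_{0:n}, N].}
#' The first two terms use plug-in (empirical frequency) estimators over
#' the ensemble; the third applies [kl_knn_entropy()] within each
#' (event count, symbol word) stratum to the vectors of completed dwells
#' (the final, censored dwell enters only through `N` and the word),
#' weighting each stratum by its frequency.  Strata with `<= k + 1`
#' members cannot support the neighbor estimate and contribute zero, with
#' a warning reporting how much weight was skipped.
#'
#' @param ensemble a [trajectory_ensemble()] with at least 50 members.
#' @param k neighbor order for the continuous term.
#' @return entropy estimate in nats.
#' @export
trajectory_entropy <- function(ensemble, k = 3L) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  seqs <- ensemble$sequences
  if (!length(seqs)) stop("empty ensemble")
  if (length(seqs) < 50)
    warning("fewer than 50 trajectories; estimates will be noisy")
  N <- vapply(seqs, n_events, integer(1))
  words <- vapply(seqs, function(s) paste(s$symbol, collapse = ""),
                  character(1))
  H_N <- plugin_discrete_entropy(N)
  strata <- split(seq_along(seqs), N)
  H_word <- 0
  for (st in strata)
    H_word <- H_word + length(st) / length(seqs) *
      plugin_discrete_entropy(words[st])
  # continuous part, stratified by (N, word)
  cells <- split(seq_along(seqs), paste(N, words, sep = ":"))
  H_tau <- 0
  skipped <- 0
  for (cell in cells) {
    w <- length(cell) / length(seqs)
    nn <- N[cell[1]]
    if (nn <= 1) next # no completed dwell: the continuous part is empty
    if (length(cell) <= k + 1) { skipped <- skipped + w; next }
    tau <- t(vapply(cell, function(i) seqs[[i]]$dwell[seq_len(nn - 1)],
                    numeric(nn - 1)))
    if (nn == 2) tau <- matrix(as.numeric(tau), ncol = 1)
    H_tau <- H_tau + w * kl_knn_entropy(tau, k = k)
  }
  if (skipped > 0)
    warning(sprintf(
      "strata holding %.1f%% of trajectories had <= k + 1 members and were skipped",
      100 * skipped))
  H_N + H_word + H_tau
}

#' Model-free differential entropy-rate estimate
#'
#' Simulates `n_traj` trajectories of the model at each window length in
#' `T_grid`, estimates the windowed entropy `H(T)` with
#' [trajectory_entropy()], and returns the asymptotic slope
#' \eqn{h_\mu = \lim_{T\to\infty} dH/dT} as the ordinary-least-squares
#' slope over the largest half of the grid (the small-`T` transient is
#' discarded).
#'
#' @param model a valid [uhsmm].
#' @param T_grid increasing vector of at least 3 window lengths.
#' @param n_traj trajectories per window length.
#' @param seed optional integer seed.
#' @param k neighbor order for the continuous entropy term.
#' @return list with `rate` (nats per unit time) and `curve`, a data frame
#'   of `T` and `H`.
#' @export
model_free_entropy_rate <- function(model, T_grid, n_traj, seed = NULL,
                                    k = 3L) {
  T_grid <- as.numeric(T_grid)
  if (length(T_grid) < 3 || is.unsorted(T_grid, strictly = TRUE))
    stop("T_grid must be at least 3 strictly increasing values")
  if (!is.null(seed)) set.seed(seed)
  H <- vapply(T_grid, function(T) {
    ens <- simulate_ensemble(model, n_traj, T)
    suppressWarnings(trajectory_entropy(ens, k = k))
  }, numeric(1))
  upper <- seq(ceiling(length(T_grid) / 2), length(T_grid))
  if (length(upper) < 2) upper <- seq_along(T_grid)
  rate <- unname(stats::coef(stats::lm(H[upper] ~ T_grid[upper]))[2])
  list(rate = rate, curve = data.frame(T = T_grid, H = H))
}
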