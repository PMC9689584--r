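test_that("plug-in rate with exact densities equals the exact formula", {
  gen <- benchmark_model("four_state")
  sim <- simulate(gen, nsim = 500, seed = 31)
  fit <- fit_topology(cycle_topology(4), sim$sequence, dwell = "kernel")
  h_exact <- entropy_rate_exact(gen)
  h_plug <- plugin_entropy_rate(fit, dwell_models = gen$dwell)
  expect_equal(h_plug, h_exact, tolerance = 1e-6)
  expect_equal(h_plug, 1.85, tolerance = 0.01)
})

test_that("plug-in rate refuses states without dwell samples", {
  gen <- benchmark_model("four_state")
  sim <- simulate(gen, nsim = 100, seed = 32)
  fit <- fit_topology(cycle_topology(4), sim$sequence, dwell = "kernel")
  fit$dwell_samples$B <- fit$dwell_samples$B[1]
  expect_error(plugin_entropy_rate(fit), "state B")
})

test_that("neighbor-distance entropy matches closed forms", {
  set.seed(33)
  x <- rnorm(10000)
  expect_equal(kl_knn_entropy(x), 0.5 * log(2 * pi * exp(1)),
               tolerance = 0.05)
  expect_equal(kl_knn_entropy(runif(10000)), 0, tolerance = 0.05)
  # scaling law: H(aX) = H(X) + log a
  expect_equal(kl_knn_entropy(10 * x) - kl_knn_entropy(x), log(10),
               tolerance = 0.05)
  # translation invariance is exact
  expect_lt(abs(kl_knn_entropy(x + 7) - kl_knn_entropy(x)), 1e-9)
  # 2-d Gaussian
  set.seed(34)
  X <- matrix(rnorm(2 * 5000), ncol = 2)
  expect_equal(kl_knn_entropy(X), log(2 * pi * exp(1)), tolerance = 0.1)
  # duplicates are jittered, not fatal
  expect_warning(kl_knn_entropy(c(1, 1, 1, 1, 2, 3, 4, 5)), "jitter")
  expect_error(kl_knn_entropy(c(1, 2, 3), k = 3), "more points than k")
})

test_that("trajectory entropy reduces to its surviving component", {
  # identical event counts and symbols: only the dwell term remains
  set.seed(35)
  n <- 300
  seqs <- lapply(seq_len(n), function(i) {
    d1 <- runif(1); event_seq(c("0", "1"), c(d1, 5 - d1), censored = TRUE)
  })
  ens <- trajectory_ensemble(seqs, 5)
  H <- trajectory_entropy(ens)
  dwells <- vapply(seqs, function(s) s$dwell[1], numeric(1))
  expect_equal(H, kl_knn_entropy(dwells), tolerance = 1e-12)
  # uniform [0, 1] first dwell: entropy near zero
  expect_equal(H, 0, tolerance = 0.1)
})

test_that("trajectory entropy is consistent with a larger reference ensemble", {
  # the neighbor estimator's negative bias shrinks with ensemble size, so
  # a moderate window keeps the two estimates close
  m <- two_state_exp()
  h_small <- suppressWarnings(
    trajectory_entropy(simulate_ensemble(m, 1000, 3, seed = 36)))
  h_big <- suppressWarnings(
    trajectory_entropy(simulate_ensemble(m, 4000, 3, seed = 37)))
  expect_lt(abs(h_small - h_big), 0.35)
})

test_that("sparse strata are skipped with a loud warning", {
  set.seed(38)
  seqs <- lapply(1:60, function(i) {
    # event counts spread thin across strata
    k <- sample(2:12, 1)
    d <- abs(rnorm(k)) + 0.05
    d <- d / sum(d) * 3
    event_seq(rep(c("0", "1"), length.out = k), d, censored = TRUE)
  })
  expect_warning(trajectory_entropy(trajectory_ensemble(seqs, 3)),
                 "skipped")
})

test_that("model-free slope approximates the exact rate of a memoryless cycle", {
  m <- two_state_exp()  # exact rate 1 nat
  # short windows keep the per-stratum dimension low, where the neighbor
  # entropy estimator is least biased; average over a few replicates
  rates <- vapply(39:41, function(s)
    model_free_entropy_rate(m, T_grid = seq(1, 3, 0.5), n_traj = 1000,
                            seed = s)$rate, numeric(1))
  mf <- model_free_entropy_rate(m, T_grid = seq(1, 3, 0.5), n_traj = 200,
                                seed = 42)
  expect_equal(nrow(mf$curve), 5)
  expect_true(all(diff(mf$curve$H) > 0))
  expect_lt(abs(mean(rates) - 1), 0.3)
  expect_error(model_free_entropy_rate(m, T_grid = c(1, 2), n_traj = 10),
               "3 strictly increasing")
})
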