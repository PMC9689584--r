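test_that("causal-state extraction uses the right-continuous convention", {
  gen <- benchmark_model("four_state")
  sim <- simulate(gen, nsim = 200, seed = 41)
  fit <- fit_topology(cycle_topology(4), sim$sequence, dwell = "kernel")
  seqd <- sim$sequence
  b1 <- seqd$dwell[1]

  cs <- extract_causal_states(fit, seqd, c(b1 / 2, b1), path = sim$states)
  expect_equal(cs$tau0, c(b1 / 2, 0))
  # at the boundary the new event is active
  expect_equal(cs$x0, seqd$symbol[1:2])
  expect_equal(cs$g, sim$states[1:2])

  # single-event sequence: tau0 is the time itself
  one <- event_seq("0", 3, censored = TRUE)
  cs1 <- extract_causal_states(fit, one, 1.2, path = "A")
  expect_equal(cs1$tau0, 1.2)

  expect_error(extract_causal_states(fit, seqd, sum(seqd$dwell) + 1,
                                     path = sim$states), "within")

  # decoded state at sampled times matches the fit's own event labeling
  # (which may be a rotation of the simulator's labels)
  times <- seq(0.1, sum(seqd$dwell) - 0.1, length.out = 50)
  cs2 <- extract_causal_states(fit, seqd, times)
  idx <- findInterval(times, cumsum(seqd$dwell)) + 1L
  expect_identical(cs2$g, fit$state_path[idx])
  # and the rotation is consistent: same permutation at every event
  perm <- unique(cbind(cs2$g, sim$states[idx]))
  expect_equal(nrow(perm), length(unique(cs2$g)))
})

test_that("neighbor prediction averages matched records deterministically", {
  train <- prediction_dataset(
    data.frame(g = c("A", "A", "A", "B"), x0 = c("0", "0", "0", "1"),
               tau0 = c(0.1, 0.2, 0.9, 0.5), stringsAsFactors = FALSE),
    future = c(0, 1, 1, 1), horizon = 0.5)
  q <- list(g = "A", x0 = "0", tau0 = 0.15)
  expect_equal(knn_predict(train, q, k = 1), 0)   # nearest: tau0 = 0.1
  expect_equal(knn_predict(train, q, k = 3), 2 / 3)
  # k larger than the match count uses all matches
  expect_equal(knn_predict(train, q, k = 10), 2 / 3)
  # no (g, x0) match: global mean with a warning
  expect_warning(
    p <- knn_predict(train, list(g = "B", x0 = "0", tau0 = 0), 1),
    "global mean")
  expect_equal(p, mean(train$future))
  # deterministic given identical inputs
  expect_identical(knn_predict(train, q, 2), knn_predict(train, q, 2))
})

test_that("neighbor prediction agrees with an exhaustive-scan oracle", {
  set.seed(42)
  n <- 400
  train <- prediction_dataset(
    data.frame(g = sample(c("A", "B"), n, TRUE),
               x0 = "0", tau0 = runif(n, 0, 5), stringsAsFactors = FALSE),
    future = runif(n), horizon = 1)
  queries <- data.frame(g = sample(c("A", "B"), 30, TRUE), x0 = "0",
                        tau0 = runif(30, 0, 5), stringsAsFactors = FALSE)
  for (k in c(1, 3, 7)) {
    pred <- knn_predict(train, queries, k)
    oracle <- vapply(seq_len(nrow(queries)), function(i) {
      sel <- train$g == queries$g[i]
      d <- abs(train$tau0[sel] - queries$tau0[i])
      mean(train$future[sel][order(d)][seq_len(k)])
    }, numeric(1))
    expect_equal(pred, oracle, tolerance = 1e-12)
    # an average of futures stays inside their range
    expect_true(all(pred >= min(train$future) & pred <= max(train$future)))
  }
})

test_that("the causal-state predictor beats persistence and hits both limits", {
  gen <- benchmark_model("four_state")
  set.seed(43)
  fit <- fit_topology(cycle_topology(4),
                      simulate(gen, nsim = 1000)$sequence, dwell = "kernel")
  tab <- evaluate_predictor(gen, fit, horizons = c(0.02, 0.5, 40),
                            n_train = 2500, n_test = 600, k = 5, seed = 44)
  w <- reshape(tab[c("horizon", "method", "mse")], idvar = "horizon",
               timevar = "method", direction = "wide")
  expect_true(all(w$mse.ctbsi <= w$mse.persistence + 0.01))
  expect_lt(w$mse.ctbsi[w$horizon == 0.02], 0.05)       # continuity at T -> 0
  expect_equal(w$mse.ctbsi[w$horizon == 40], 0.25,      # mixing limit
               tolerance = 0.06)
})
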