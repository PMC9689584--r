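test_that("validate_model accepts valid machines and names each violation", {
  expect_identical(validate_model(benchmark_model("four_state")),
                   character(0))
  expect_identical(validate_model(benchmark_model("three_state_multi")),
                   character(0))

  # successor allowed to re-emit the same symbol: alternation broken
  bad_top <- uhsmm_topology(
    states = c("A", "B"), alphabet = c("0", "1"),
    emissions = list(A = "0", B = c("0", "1")),
    successor = list(A = list("0" = "B"),
                     B = list("0" = "A", "1" = "A")))
  v <- validate_model(bad_top)
  expect_true(any(grepl("state A.*symbol 0", v)))

  # emission probabilities not summing to one
  m <- benchmark_model("three_state_multi")
  m$emission_prob$A <- c("0" = 0.5, "1" = 0.4)
  v <- validate_model(m)
  expect_length(v, 1)
  expect_match(v, "state A.*sum to 0.9")

  # unreachable state
  top <- uhsmm_topology(
    states = c("A", "B", "C"), alphabet = c("0", "1"),
    emissions = list(A = "0", B = "1", C = "1"),
    successor = list(A = list("0" = "B"), B = list("1" = "A"),
                     C = list("1" = "A")))
  expect_true(any(grepl("unreachable", validate_model(top))))
})

test_that("simulation alternates symbols and honors each horizon kind", {
  m2 <- two_state_exp()
  sim <- simulate(m2, nsim = 5, seed = 1)
  expect_equal(nchar(paste(sim$sequence$symbol, collapse = "")), 5)
  expect_true(all(sim$sequence$symbol[-1] != sim$sequence$symbol[-5]))
  expect_false(attr(sim$sequence, "censored"))

  # alternation across random models and seeds
  for (seed in 1:20) {
    m <- random_cycle_model(seed)
    s <- simulate(m, nsim = 50, seed = seed)$sequence$symbol
    expect_true(all(s[-1] != s[-length(s)]))
  }

  # identical seed, identical output
  a <- simulate(m2, nsim = 20, seed = 7)
  b <- simulate(m2, nsim = 20, seed = 7)
  expect_identical(a, b)

  # duration horizon truncates and censors
  md <- uhsmm(cycle_topology(2),
              dwell = list(A = dwell_uniform(20, 30),
                           B = dwell_uniform(20, 30)))
  simd <- simulate(md, duration = 10, seed = 2)
  expect_equal(nrow(simd$sequence), 1)
  expect_true(attr(simd$sequence, "censored"))
  expect_equal(sum(simd$sequence$dwell), 10)

  expect_error(simulate(m2, duration = 0), "positive")
  expect_error(simulate(m2, nsim = 0), "positive")
})

test_that("simulated mean dwell matches the cycle average", {
  m <- benchmark_model("four_state")
  sim <- simulate(m, nsim = 10000, seed = 42)
  se <- sd(sim$sequence$dwell) / sqrt(10000)
  expect_lt(abs(mean(sim$sequence$dwell) - 2), 3 * se)
})

test_that("unifilar decoding follows the successor map and round-trips", {
  top <- cycle_topology(4)
  seq4 <- event_seq(c("0", "1", "0", "1"), rep(1, 4))
  expect_identical(decode_states(top, seq4, "A"), c("A", "B", "C", "D"))

  # failure carries the offending event index
  err <- tryCatch(decode_states(top, seq4, "B"),
                  ctbsi_decode_error = function(e) e)
  expect_s3_class(err, "ctbsi_decode_error")
  expect_equal(err$index, 1)

  for (seed in 1:100) {
    m <- random_cycle_model(seed)
    sim <- simulate(m, nsim = 40, seed = seed + 1000)
    expect_identical(decode_states(m$topology, sim$sequence, sim$states[1]),
                     sim$states)
  }
})

test_that("stationary weights solve the mean-dwell-weighted balance", {
  # symmetric 2-cycle
  m2 <- two_state_exp()
  expect_equal(stationary_distribution(m2), c(A = 0.5, B = 0.5))

  # deterministic cycle: p(s) proportional to 1 / mu_s
  p <- stationary_distribution(benchmark_model("four_state"))
  expect_equal(p, c(A = 0.375, B = 0.125, C = 0.125, D = 0.375))

  # single absorbing self-loop reduces to normalization
  expect_equal(stationary_distribution(c(S = 2),
                                       matrix(1, 1, 1,
                                              dimnames = list("S", "S"))),
               c(S = 1))

  # fixed point of the recursion, probability vector, across random models
  for (seed in 1:25) {
    m <- random_cycle_model(seed)
    states <- m$topology$states
    mu <- vapply(m$dwell, dwell_mean, numeric(1))[states]
    P <- diag(length(states))[c(seq_along(states)[-1], 1), ]
    dimnames(P) <- list(states, states)
    p <- stationary_distribution(setNames(mu, states), P)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    resid <- as.numeric((t(P) * outer(1 / mu, mu)) %*% p) - p
    expect_lt(max(abs(resid)), 1e-10)
  }

  # reducible structure is refused with the unreachable states named
  P <- matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(stationary_distribution(c(A = 1, B = 1), P), "reducible")
})

test_that("exact entropy rate reproduces closed forms and is grid-stable", {
  expect_equal(entropy_rate_exact(two_state_unif()), 0, tolerance = 1e-9)
  # unit-mean exponential dwells: differential entropy 1 nat per state
  expect_equal(entropy_rate_exact(two_state_exp()), 1, tolerance = 1e-6)

  h <- entropy_rate_exact(benchmark_model("four_state"))
  h_refined <- entropy_rate_exact(benchmark_model("four_state"),
                                  rel.tol = 1e-12)
  expect_lt(abs(h - h_refined), 1e-3)

  bad <- two_state_exp()
  bad$emission_prob$A <- c("0" = 0.5)
  expect_error(entropy_rate_exact(bad), "invalid model")
})

test_that("event TSV and model JSON round-trip", {
  tsv <- tempfile(fileext = ".tsv")
  s <- event_seq(c("0", "1", "0"), c(1.25, 0.5, 2e-3), censored = TRUE)
  write_events(s, tsv)
  s2 <- read_events(tsv)
  expect_equal(s2$symbol, s$symbol)
  expect_equal(s2$dwell, s$dwell)
  expect_true(attr(s2, "censored"))

  writeLines(c("symbol\tdwell", "0\t1.0", "0\t2.0"), tsv)
  expect_error(read_events(tsv), "consecutive")
  writeLines(c("symbol\tdwell", "0\t-1.0"), tsv)
  expect_error(read_events(tsv), "positive")

  js <- tempfile(fileext = ".json")
  m <- benchmark_model("three_state_multi")
  write_model(m, js)
  m2 <- read_model(js)
  expect_identical(m2$topology, m$topology)
  expect_equal(m2$emission_prob, m$emission_prob)
  expect_equal(m2$dwell$A$mu, 1)
  expect_equal(m2$dwell$B$lambda, 3)
  # parametric round trip is bit-exact
  expect_identical(ddwell(m2$dwell$C, c(0.5, 1, 2)),
                   ddwell(m$dwell$C, c(0.5, 1, 2)))
})

test_that("event sequences reject invalid construction", {
  expect_error(event_seq(c("0", "0"), c(1, 1)), "consecutive")
  expect_error(event_seq("0", 0), "positive")
})
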