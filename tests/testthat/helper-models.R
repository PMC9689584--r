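# shared fixtures, all built in code

# a cheap training configuration for unit tests of the neural estimator
quick_config <- function(epochs = 200L, seeds = 1L, lr = 1e-3)
  density_fit_config(layers = 4L, width = 5L, epochs = epochs,
                     seeds = seeds, integration_grid = 256L,
                     learning_rate = lr)

# 2-cycle with unit-mean exponential dwells: exact entropy rate 1 nat
two_state_exp <- function()
  uhsmm(cycle_topology(2),
        dwell = list(A = dwell_exponential(1), B = dwell_exponential(1)))

# 2-cycle with uniform [0, 1] dwells: exact entropy rate 0
two_state_unif <- function()
  uhsmm(cycle_topology(2),
        dwell = list(A = dwell_uniform(0, 1), B = dwell_uniform(0, 1)))

# random even binary cycle with random inverse-Gaussian dwells
random_cycle_model <- function(seed) {
  set.seed(seed)
  n_states <- sample(c(2L, 4L, 6L), 1)
  top <- cycle_topology(n_states)
  dwell <- lapply(top$states, function(s)
    dwell_invgauss(runif(1, 0.5, 4), runif(1, 0.5, 6)))
  names(dwell) <- top$states
  uhsmm(top, dwell = dwell)
}
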