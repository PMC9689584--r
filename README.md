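# ctbsi — continuous-time Bayesian structural inference

`ctbsi` infers interpretable state-machine models of **continuous-time,
discrete-event processes** — neural spike trains, animal behavior logs,
seismic catalogs: any record of the form *symbol, held for a duration;
next symbol, held for a duration; …* — and uses the inferred model to
estimate the process's intrinsic randomness and to predict its future.

The model class is the **unifilar hidden semi-Markov model** (uhsMm, an
ε-machine): a finite hidden state $g$ emits a symbol
$x \sim p(\cdot \mid g)$ for a dwell time $\tau \sim \phi_g(\tau)$, then
moves deterministically to $\epsilon^+(g, x)$.  Unifilarity means the
hidden path is a *function* of the observations and a start state, which
makes three classically hard tasks tractable:

1. **Model inference.**  For each candidate topology, decode the hidden
   path, fit each state's dwell density $\phi_g$ with a normalized neural
   estimator trained by maximum likelihood, take the closed-form emission
   maximizers, and select the topology minimizing
   $\mathrm{BIC} = \frac{k_M}{2}\log|D| - \max_\theta \log L$.
2. **Entropy-rate estimation.**  Plug decoded dwell statistics into
   $h_\mu = -\sum_s p(s)\int_0^\infty \mu_s \phi_s(t)\log\phi_s(t)\,dt$
   with state weights solving
   $p(s) = \sum_{s'} \frac{\mu_{s'}}{\mu_s}\frac{n_{s'\to s}}{n_{s'}}p(s')$;
   or, model-free, estimate the slope of the windowed trajectory entropy
   $H[(x,\tau)_{0:T}]$ via plug-in and Kozachenko–Leonenko
   k-nearest-neighbor entropy estimators.
3. **Prediction.**  The triple $(g, x_0, \tau_0^+)$ — hidden state,
   current symbol, time since the last change — is a sufficient statistic
   (causal state); a conditional k-nearest-neighbor rule on it estimates
   the symbol a horizon $T$ ahead.

Everything runs on synthetic data from the package's own benchmark
generators; no external data is required.

## Worked example

```r
library(ctbsi)

model <- benchmark_model("four_state")   # A(0)->B(1)->C(0)->D(1)->A cycle
model
#> <uhsmm> 4 states over {0,1}
#>   A: emits {0}, dwell invgauss (mean 1)
#>   B: emits {1}, dwell invgauss (mean 3)
#>   C: emits {0}, dwell invgauss (mean 3)
#>   D: emits {1}, dwell invgauss (mean 1)

entropy_rate_exact(model)
#> [1] 1.848745
```

The exact differential entropy rate of this benchmark generator is
**1.85 nats** — the package's headline reproducible number, which pins
down the convention of the plug-in formula above.

```r
sim <- simulate(model, nsim = 3000, seed = 7)
cfg <- density_fit_config(layers = 4, width = 5, epochs = 400, seeds = 1,
                          integration_grid = 256)
sel <- select_model(sim$sequence, enumerate_topologies(c("0", "1"), 6), cfg)
sel$table
#>   topology_id n_states n_params    loglik      bic selected
#> 1      cycle2        2       92 -4565.419 4933.712    FALSE
#> 2      cycle4        4      184 -3855.094 4591.679     TRUE
#> 3      cycle6        6      276 -4468.892 5573.771    FALSE
```

With 3000 events, BIC correctly selects the four-state cycle: the
two-state model merges two distinct dwell distributions per state and
loses ~710 nats of likelihood, far more than the 184-parameter penalty;
the six-state model gains nothing and pays more.

```r
fit <- fit_topology(cycle_topology(4), sim$sequence, dwell = "kernel")
plugin_entropy_rate(fit)
#> [1] 1.91602
```

The model-based plug-in estimate (Parzen dwell densities on the decoded
per-state dwells) lands within 0.07 nats of the exact 1.8487 at this
sample size.

```r
evaluate_predictor(model, fit, horizons = c(0.1, 1), n_train = 3000,
                   n_test = 500, k = "cv", seed = 8)
#>   horizon      method       mse  k
#> 1     0.1       ctbsi 0.0428744 50
#> 2     0.1 persistence 0.0480000 NA
#> 3     1.0       ctbsi 0.1989440 50
#> 4     1.0 persistence 0.3620000 NA
```

The causal-state predictor beats the persistence baseline (forecast the
current symbol) at every horizon; at short horizons both are nearly
optimal, at long horizons persistence decays to 0.5 while the causal-state
rule approaches the stationary symbol variance 0.25.

Scripted end-to-end experiments (density estimation, model selection,
entropy-rate comparison, prediction) are available via
`run_experiment("selection", scale = 0.2, seed = 1)`, and from the shell
through the thin CLI in `inst/cli/ctbsi.R`.  The methods vignette
(`vignettes/ctbsi-methods.Rmd`) documents the model class, estimators,
conventions and the validation study conditions.

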