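# abcpa

Likelihood-free Bayesian parameter inference and model selection for
dynamic models of biochemical networks, by **population annealing** in the
**approximate Bayesian computation (ABC)** framework.

The package is for systems-biology modellers who have an ODE model (or a
pair of competing models), a short noisy time series, and no tractable
likelihood: it produces a posterior *parameter ensemble* for simulation,
an estimate of the ABC marginal likelihood for each model, and the Bayes
factor between two models — together with an ABC rejection-sampler
baseline, trajectory credible bands, and a generator of artificial
observed data. The built-in case study is the coherent vs incoherent
feed-forward-loop (FFL) transcription motif.

## The method

ABC replaces the likelihood by simulation: with observed data
`D_obs`, simulated data `D_sim | θ`, distance
`d(D_obs, D_sim) = Σ_t (obs_t − sim_t)²` and tolerance `ε`, the target is
the augmented posterior

```
π_ABC(θ, D_sim | D_obs, M) ∝ 1{ d(D_obs, D_sim) ≤ ε } f(D_sim | θ, M) π(θ | M)
```

Population annealing drives K weighted particles through the
tolerance-indexed sequence of intermediate distributions
`f_IM^n(θ) ∝ π(θ|M) · 1{d ≤ ε_n}` for a strictly decreasing schedule
`ε_0 = ∞ > ε_1 > … > ε_N`:

1. **PA1** — draw `θ^k ~ π(θ|M)`, set `w_0^k = 1/K`;
2. **PA2**, for `n = 1..N`:
   (a) reweight by the indicator `1{d^k ≤ ε_n}` and normalize;
   (b) rejuvenate every surviving particle by a fixed number of ABC-MCMC
       moves stationary for `f_IM^n`;
   (c) if the effective sample size `ESS = 1/Σ_k (w^k)²` has fallen below
       `K/2`, record the survivor count `k_resample` and resample K
       particles multinomially.

Because the indicator makes all surviving weights equal, the surviving
fraction is an acceptance probability, and

```
P_ABC(D_obs | M) ≈ [ Π over resampling events k_resample/K ] × (final survivors)/K
```

estimates the ABC marginal likelihood. For two models fitted to the same
data at the same final tolerance, the ratio of these estimates is the
Bayes factor `B_12^ABC`. The final weighted ensemble is used *en masse*
("posterior parameter ensemble"): one trajectory per particle, summarized
by pointwise weighted quantile bands — including prediction runs under
inputs that were never used for fitting.

## Worked example

Fit the coherent FFL model to the bundled step-response data, inspect the
run, and compare the two FFL topologies by Bayes factor:

```r
library(abcpa)
obs <- load_fixture("step_obs")                 # 10 noisy Z observations, t = 1..10
model <- ffl_model("coherent_ffl")
fit <- run_pa(model, ffl_default_prior(), obs,
              ffl_schedules()$AS2, K = 10000, seed = 1)
fit
#> <pa_result> coherent_ffl
#>   schedule: ( Inf, 1.00, 0.50, 0.25, 0.20, 0.15)
#>   K = 10000, mcmc_steps = 7
#>   ABC marginal likelihood: 0.0155669
#>   resampling events (level: k_resample):  1: 1199, 3: 2522
```

About 1.6% of prior-predictive simulations fall within `ε = 0.15` of the
data (the product `0.1199 × 0.2522 × 0.5148`); the resampling log shows
the ensemble was rebuilt after the `ε = 1` and `ε = 0.25` levels.

```r
dens <- simulate_ensemble(fit$ensemble, model)  # posterior trajectory bands
coverage(dens, obs)                             # min-max envelope coverage
#> [1] 1

bf <- repeated_bayes_factor(ffl_model("coherent_ffl"),
                            ffl_model("incoherent_ffl"),
                            ffl_default_prior(), obs,
                            ffl_schedules()$AS1, K = 10000,
                            n_repeats = 3, root_seed = 1)
bf
#> <bf_result> coherent_ffl vs incoherent_ffl (pa)
#>   schedule: ( Inf, 2.00, 1.00, 0.75, 0.50, 0.25), last eps = 0.25
#>   K = 10000, repeats = 3 (degenerate: 0)
#>   Bayes factor: 1.657 +/- 0.102
```

Every observed point lies inside the ensemble envelope, and the Bayes
factor exceeds 1: the data (generated from the coherent topology) favour
the coherent model, increasingly so as the final tolerance tightens.

A thin command-line wrapper is installed as `inst/scripts/abcpa`
(subcommands `gen-data`, `pa-infer`, `abc-reject`, `bayes-factor`,
`ensemble-sim`), driven by YAML/JSON config files.

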