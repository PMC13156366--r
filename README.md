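# misscvae

Imputation-free survival prediction from incomplete covariates.

Routinely collected clinical data (electronic health records) have
structured gaps: which laboratory panels get measured depends on how sick a
patient is, so the missingness pattern itself carries outcome signal
(missing-not-at-random). Prediction models face this at deployment — the
outcome is unknown, imputation models may not travel with the model, and new
patients arrive with missingness patterns never seen in training.

`misscvae` handles this by *modelling* the missingness rather than imputing
it away. A two-tiered variational autoencoder embeds the binary mask
`m ∈ {0,1}^p` into a latent `h_m`, and — conditionally on `h_m` — the
observed covariates `x̃` (NA-marked, zero-filled after standardisation) into
`h_x`. Both embeddings feed a monotone neural survival head

    S(t | x̃, m) = 1 − tanh( ∫₀ᵗ g(u, h_x, h_m) du ),   g ≥ 0,

trained end-to-end against a weighted evidence lower bound

    α·(right-censored NLL) + β·(masked reconstruction) + γ·(KL),

with α = 10, β = γ = 0.1: the survival likelihood contributes the density at
event times and the survival at censoring times; covariate reconstruction is
computed on observed entries only (imputation is not a product of the
model); the KL terms regularise toward the standard-normal prior. Prediction
uses posterior means only, so deployment is deterministic and total: any
missingness pattern, including all-missing rows, yields a valid curve.

The package also ships:

* an MNAR survival-data **simulator** (latent health/lifestyle variables →
  correlated risk factors → proportional-hazards outcomes by inverse
  sampling → latent-threshold missingness with block covariance), with
  closed-form ground-truth survival curves and three evaluation scenarios
  (baseline, unseen patterns, missingness shift);
* nine **baseline strategies** (column-wise deletion, deletion + mask, mean
  fill, regression imputation, chained equations, MICE with and without
  outcome proxies, −1 encoding, missing-indicator method), all feeding the
  identical survival head;
* five **metrics**: time-dependent concordance, IPCW Brier score and
  negative binomial log-likelihood (integrated), right-censored
  log-likelihood, and integrated squared error against the simulation
  oracle;
* an experiment **harness** (scenarios × methods × seeds, per-cell caching,
  mean (sd) tables, top-rank counts) and a thin CLI
  (`inst/cli/misscvae.R simulate|train|predict|benchmark|report`).

## Worked example

```r
library(misscvae)

spec <- default_simulation_spec(n = 2000)          # 20 factors, 15 partially observed
scenario <- build_scenario("baseline", spec, seed = 42)

model <- misscvae_fit(scenario$split$train, scenario$split$validation,
                      misscvae_config(epochs = 20), seed = 42)

grid <- make_eval_grid(scenario$split$test$time)   # 0 .. 90th pct of test times
curves <- predict(model, scenario$split$test, grid)
curves
#> survival_curves: 400 subjects on 100 grid points [0, 40.6224]

round(evaluate_all(curves, scenario$split$test$time,
                   scenario$split$test$event, scenario$ground_truth_test), 3)
#>   ctd   ibs inbll   nll   ise
#> 0.790 0.141 0.433 2.380 0.025

new_patient <- scenario$split$test[3]              # 3 of 20 covariates missing
round(predict(model, new_patient, c(0, 5, 10, 20))$surv, 3)
#>      [,1]  [,2]  [,3]  [,4]
#> [1,]    1 0.598 0.308 0.064
```

Discrimination (`ctd` 0.79) reads like a C-index; `ibs`/`inbll` are
censoring-adjusted calibration-plus-discrimination scores (lower is better);
`nll` is the proper right-censored log-likelihood; `ise` is the mean squared
gap to the true simulated curves, available only because the simulator knows
them — here the average predicted curve sits within about `sqrt(0.025) ≈
0.16` of the truth pointwise. The single-patient call shows deployment:
one incomplete row in, one survival curve out, no imputation model needed.

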