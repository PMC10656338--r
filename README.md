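# wpscausal

Two-step causal inference for **joint effects of time-varying continuous
treatments at the within-person level**, for longitudinal panels where
stable between-person differences would otherwise confound the estimates.

Behavioural and epidemiological panels mix two kinds of association: stable
traits (a person who chronically sleeps little may also be chronically more
symptomatic) and within-person dynamics (a spell of short sleep preceding a
worse outcome). `wpscausal` targets the latter. Each variable on a fixed
grid `t_0..t_K` is decomposed as

    X_ik = mu_k + I_i + X*_ik

with a stable-trait factor `I_i` (random intercept, loading one at every
wave) uncorrelated with the within-person variability score `X*_ik`. The
causal estimand is the coefficient vector in
`E(Y*_k under a-bar) = sum_t beta_kt a*_t` — the joint effect of shifting
each treatment one unit from the person's own expected level.

Estimation proceeds in two steps:

1. **Score prediction.** Per variable, the single-factor measurement model
   `Sigma = phi^2 11' + Psi(theta)` (time-varying AR(1) within-covariance by
   default) is fitted by maximum likelihood (FIML under MAR), and
   within-person scores are predicted with the best linear
   correlation-preserving predictor
   `W' = Psi^{1/2}(Psi^{3/2} Sigma^{-1} Psi^{3/2})^{-1/2} Psi^{3/2} Sigma^{-1}`,
   which reproduces the within-covariance (`W' Sigma W = Psi`) while
   minimizing mean squared error.
2. **Causal estimation.** On the predicted scores, either a marginal
   structural model fitted by stabilized inverse-probability weighting for
   continuous treatments (normal density ratios), or a linear structural
   nested mean model fitted by doubly robust G-estimation, optionally with
   treatment-by-confounder moderation (blips
   `(beta_ml + gamma_ml l*) a*_l`).

The package also ships the benchmark first-order linear data-generating
process with its misspecification scenarios, an analytic path-tracing
oracle for the true joint effects of any such process, and a Monte-Carlo
study runner comparing centering strategies (latent truth, two-step
prediction, observed person means, no centering, trait-prediction
centering) by bias and RMSE.

## Worked example

Simulate a benchmark panel (1000 persons, five waves, trait share 50% of
the initial measurement variance), run the two-step pipeline, and compare
with the analytic truth:

```r
library(wpscausal)

spec  <- dgp_spec(N = 1000, K = 4, phi2 = 10, seed = 42)
panel <- simulate_panel(spec)
panel
#> panel_data: 1000 persons, grid t0..t4, 3 variables
#>   Y [outcome]: occasions 0..4, 0.0% missing
#>   A [treatment]: occasions 0..3, 0.0% missing
#>   L [confounder]: occasions 0..4, 0.0% missing

pipe <- run_pipeline(panel, centering = "proposed")
pipe
#> two-step pipeline (proposed centering)
#>    method parameter estimate se
#> 1    snmm  beta_1_0  0.48824 NA
#> 2    snmm  beta_2_0  0.16484 NA
#> 3    snmm  beta_3_0  0.13797 NA
#> 4    snmm  beta_4_0 -0.01805 NA
#> 5    snmm  beta_2_1  0.43373 NA
#> 6    snmm  beta_3_1  0.22655 NA
#> 7    snmm  beta_4_1  0.15214 NA
#> 8    snmm  beta_3_2  0.39328 NA
#> 9    snmm  beta_4_2  0.14986 NA
#> 10   snmm  beta_4_3  0.35900 NA
#> ...

true_joint_effects(dgp_coefficients(), K = 4)
#> True joint effects of within-person treatment impulses
#>   E(Y*_4): a0=0.0486 a1=0.09 a2=0.18 a3=0.4  (joint 0.7186)
#>   E(Y*_3): a0=0.09 a1=0.18 a2=0.4  (joint 0.67)
#>   E(Y*_2): a0=0.18 a1=0.4  (joint 0.58)
#>   E(Y*_1): a0=0.4  (joint 0.4)
```

`beta_k_t` is the effect on the outcome score at wave `k` of a one-unit
within-person increase of the treatment at occasion `t`. On this single
panel the estimates track the truth (e.g. `beta_4_3` 0.36 vs 0.40,
`beta_1_0` 0.49 vs 0.40); the measurement model is deliberately an AR(1)
approximation to a richer process, so a small attenuation/inflation
pattern remains, which the study runner quantifies against the alternative
centerings (pass `nboot = 500` for bootstrap standard errors):

```r
cfg <- study_config(N = 1000, K = 4, phi2 = 10, replications = 50,
                    centerings = c("true_score", "proposed",
                                   "observed_mean", "none"))
print(run_simulation_study(cfg))
```

A thin command-line front end over the same functions is installed at
`system.file("cli/wpscausal.R", package = "wpscausal")` with subcommands
`simulate`, `predict-scores`, `fit-msm`, `fit-snmm`, `oracle` and
`run-study`.

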