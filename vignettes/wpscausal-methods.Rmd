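---
title: "Within-person variability score causal inference: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-person variability score causal inference: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

Longitudinal observational panels confound two sources of association
between a time-varying treatment $A$ and an outcome $Y$: stable
between-person differences (people who chronically sleep little may also be
chronically more symptomatic) and genuine within-person dynamics (a night of
short sleep preceding a worse week). `wpscausal` estimates joint causal
effects of a *sequence* of continuous treatments on later outcomes **at the
within-person level**, controlling for stable traits without modeling the
within-person structural relations parametrically.

The model for each observed variable $X \in \{Y, A, L_1, \dots\}$ on a fixed
grid $t_0 \dots t_K$ is an additive decomposition

$$X_{ik} = \mu_k + I_i + X^*_{ik},$$

where $I_i$ is a time-invariant *stable trait* (a random intercept with
loading one at every wave, uncorrelated with the within-person scores) and
$X^*_{ik}$ is the *within-person variability score*, the temporal deviation
of person $i$ from their own expected level $\mu_k + I_i$. The causal
estimand is the coefficient vector $\beta_{kt}$ in
$E(Y^{*\,\bar a}_{k}) = \sum_{t<k} \beta_{kt}\, a^*_t$: the joint effect of
setting each treatment's within-person deviation. Identification requires
the decomposition above, first-order dependence of the within-person
process on its own past (with homogeneous coefficients), consistency,
sequential ignorability, SUTVA, positivity, modularity, and multivariate
normality where maximum likelihood is used in step 1.

Estimation is deliberately split in two steps so that misspecification of
the structural (within-person) part cannot contaminate the measurement
part, and vice versa:

1. **Measurement step.** Per variable, fit
   $\Sigma = \phi^2 \mathbf{1}\mathbf{1}^t + \Psi(\theta)$ by ML
   (`fit_measurement_model()`), predict stable traits with the linear
   correlation-preserving predictor (`predict_stable_traits()`), form
   $\hat\Psi = S - \hat\Phi^+$ (`estimate_within_covariance()`), and predict
   scores $\hat X^*_i = W^t(X_i - \bar X)$ with the minimum-MSE weights
   satisfying $W^t \Sigma W = \Psi$ (`cpp_weights()`).
2. **Causal step.** On the predicted scores, fit either a marginal
   structural model by stabilized inverse-probability weighting for
   continuous treatments (`msm()`) or a linear structural nested mean model
   by G-estimation (`snmm()`), the latter doubly robust in its two nuisance
   models and able to carry treatment-by-confounder moderation terms.

## Step-1 modeling choices

**Covariance structures.** $\Psi(\theta)$ must be restricted for
identification. The default `ar1_timevarying` (free initial variance, one
autoregressive coefficient per transition, one innovation variance per
occasion) is flexible enough to absorb the nonstationarity that a
first-order within-person process started off its stationary distribution
exhibits, while staying identified for $K \ge 2$ (three waves leave the
covariance structure just-identified). `ar1_stationary`,
`compound_symmetry` and `toeplitz` are provided for sensitivity analysis;
note that compound symmetry is only weakly separated from the trait
variance, since both add a constant to every covariance. With only two
waves of a variable the free AR(1) structure is not identified; the
`equal_ar`/`equal_resid` flags equate parameters across occasions instead
of silently picking a point on the ridge.

**Unconstrained variances and improper solutions.** Variance parameters are
estimated *unconstrained* (quasi-Newton from three deterministic starting
points: moment-based, shrunk, diffuse; non-positive-definite $\Sigma$ is
repelled by a smooth penalty). A solution with any negative variance
estimate — trait, initial or innovation — is flagged `improper` and the
study runner discards that replication. Estimating on the log scale would
have guaranteed positivity but turns the improper-solution *rate*, a
diagnostic quantity of interest, into an artifact of an arbitrary bound.

**Missing data.** Under MAR the default is casewise (full-information) ML
over each person's observed coordinates; complete-case analysis is
available. Score prediction restricts $S$, $\hat\Phi^+$ and the weight
construction to each person's observed coordinates, so persons contribute
pattern-specific weights $W_i$ and scores exist only at observed cells.
CFI/RMSEA/SRMR are computed from complete-data sufficient statistics; with
actual missingness they are reported `NA` rather than pretending a
saturated FIML baseline was fitted.

**Sample versus model-implied moments.** $\mu$ and $\Sigma$ entering the
score predictor are the sample mean and covariance by default (the
model-implied $\hat\Sigma(\theta)$ is available via `sigma = "model"`), so
the weights inherit as little structure as possible from the fitted model.
$\hat\Psi = S - \hat\Phi^+$ is not guaranteed PSD in finite samples; it is
eigenvalue-clipped at $10^{-8}$ with a warning whenever a materially
negative eigenvalue had to be repaired.

**Non-orthogonality of the predictors.** The latent trait and scores are
uncorrelated by construction, but their *linear predictors* are not at
small $K$: the trait predictor necessarily carries part of the person's
within-person average, and the population cross-covariance
$w_I^t \Sigma W$ is positive (correlation around 0.7 at four waves with a
50% trait share), shrinking only as the number of waves grows. The test
suite therefore checks the predictors against this analytic value and
checks orthogonality only for the latent quantities.

## Step-2 modeling choices

**Stabilized weights.** Treatment-assignment densities are normal-linear
per occasion: numerator $f(A^*_t \mid A^*_{t-1})$, denominator
$f(A^*_t \mid A^*_{t-1}, Y^*_t, L^*_t)$ (the outcome score is part of the
confounder history; a quadratic outcome term is optional). The weight for
the outcome at horizon $k$ multiplies the density ratios over intervened
occasions $t \le k-1$. The earliest intervened occasion **is weighted by
default** (its numerator is the marginal density): leaving it unweighted —
a reading the empty-product convention $w_{i1} = 1$ invites — makes the
horizon-1 coefficient inconsistent whenever the initial treatment is
confounded by the initial state (under the benchmark process it would
converge to 0.55 instead of 0.40). `include_initial = FALSE` reproduces the
unweighted-first-occasion convention for comparison. Weights are not
truncated by default; percentile truncation is available and recorded.

**Rank deficiency.** The per-horizon weighted regression flags a
rank-deficient design and reports the affected coefficients as unavailable
instead of silently dropping columns. This matters for observed-mean
centering: with the treatment observed at $K$ occasions, the $K$ centered
treatment columns sum to zero exactly, so the horizon-$K$ joint effect is
unidentified by construction.

**G-estimation.** The linear identity-link blip
$h_{l,m} = (\beta_{ml} + \sum_j \gamma_{mlj} L^*_{jl}) A^*_l$ vanishes at
the reference level $a^* = 0$ (the person's own expected level). The
estimating equations set empirical conditional covariances between the
treatment residual from nuisance model A and the model-B residual of the
blip-removed outcome $U^*(\tau)$ to zero, weighted by reciprocal residual
variances (the locally efficient choice under homoscedasticity;
conditional expectations are evaluated in closed form under the
linear-normal model A rather than by simulation). The variance weights are
frozen during each Newton loop — the equations are then affine in $\tau$
and solve in one step — and refreshed in a short outer loop (3 updates;
residual-norm tolerance $10^{-10}$; central-difference Jacobian, step
$10^{-6}$). Either nuisance model can be deliberately reduced
(`b_terms = "reduced"`) or enriched (`a_quadratic = TRUE`) to exercise
double robustness.

**Standard errors.** The reference analysis reports uncertainty, but the
method for it is an open choice; the package implements person-level
nonparametric bootstrap (`nboot`, suggested 500). The fitting functions
default to `nboot = 0` so that Monte-Carlo studies, which need only point
estimates, do not pay for resampling.

## What the synthetic generator emulates — and what it does not

`simulate_panel()` draws initial within-person scores with variances 10 and
covariances 3, advances them through a first-order linear process (outcome
and confounder equations lagged; the treatment equation contemporaneous in
the outcome and confounder, which are measured before the treatment at each
occasion; all innovation variances 5), draws correlated stable traits
(default correlation 0.3, variances $10/9$, $30/7$ or $10$, i.e. trait
shares of 10/30/50% of the initial measurement variance) independently of
the scores, and adds the two. Three misspecification scenarios cover
measurement error (10 or 20% of the initial measurement variance),
time-varying/cross loadings from the time-invariant factors (so they are no
longer pure stable traits), and a quadratic confounder term (coefficient
0.08) in the treatment assignment. Treatments are generated at occasions
$0 \dots K-1$; `treatment_waves = "all"` adds the final wave for
cohort-style panels where the treatment variable is simply measured every
wave (and is needed for the measurement model of a three-wave panel to be
identified). An optional monotone MAR dropout generator (logit hazard on
the previous outcome) is off by default: the benchmark study uses complete
data.

Two caveats the generator makes explicit rather than hiding:

* **The benchmark process is not stationary.** With the initial covariance
  fixed at (10, 3) and innovation variance 5, the exact covariance path
  (`implied_covariance_path()`) drifts from variance 9.74 at the first
  transition to about 12.2 by wave 4, toward a stationary solution
  (`stationary_within_covariance()`) with variances near 14.2. "Score
  variance stays near 10" is therefore only approximately true at early
  waves, and the package reports the drift rather than re-tuning the
  process. The causal coefficients are path coefficients and are unaffected.
* **The AR(1) measurement structure is misspecified for this process** (the
  marginal series of one variable from a trivariate first-order system is
  not AR(1)), so the trait variance estimate is biased upward under large
  trait shares and the proposed centering inherits a visible but small bias
  — precisely the regime the comparative study quantifies. Passing
  recovery tests on model-true data plus small comparative bias here does
  not certify performance on real data whose decomposition assumption
  itself may fail (e.g. traits correlated with scores through shared
  causes).

The generator is seeded and bit-reproducible; the study runner derives the
seed of replication $r$ as `base_seed + r`.

## Analytic effects oracle

`true_joint_effects()` computes the implied $\beta_{kt}$ for any
first-order linear coefficient set by severing the treatment equations in
the intervention window and propagating a unit treatment impulse through
the outcome/confounder subsystem; the one-step effect equals the
cross-lagged coefficient. For the default coefficients and $K = 4$ this
gives $(0.0486, 0.09, 0.18, 0.40)$ at horizon 4, and an eight-wave design
intervening on the last four occasions reproduces the same ten values. A
seeded interventional simulation (`simulate_counterfactual()`, common
random numbers across arms so the Monte-Carlo noise cancels exactly)
cross-checks the recursion in the tests.

## Problem sizes used by the tests and the acceptance script

Chosen as desk-scale defaults that keep the full suite in minutes while
leaving Monte-Carlo error well below the effects being compared: the
comparative bias/efficiency study runs $N = 1000$, $K = 4$ and $8$,
$\phi^2 = 10$, 50 replications per cell (the full protocol of record is
200); double robustness runs $N = 2000$, 30 replications; the
improper-solution rate scans the full $3 \times 2 \times 3$ grid at 50
replications (2700 covariance fits); calibration checks use $N = 20000$.
At 50 replications the per-parameter Monte-Carlo standard error of the
IPW-MSM bias is about 0.008–0.011, so comparisons at the 0.02 level for
that estimator are near the resolution limit — the G-estimator, with
roughly half the RMSE, is not affected.

## Known limitations

* Single outcome, single treatment, continuous treatments only; logistic
  or log-link structural nested models are out of scope.
* No MNAR machinery; FIML is only valid under MAR.
* The bootstrap is the only uncertainty method provided; no closed-form
  sandwich variances.
* Fit indices are unavailable under genuine missingness (by design, see
  above).
* Two-wave variables require equality constraints in the measurement
  model; the package warns rather than guessing.
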