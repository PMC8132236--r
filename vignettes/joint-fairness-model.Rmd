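---
title: "Joint fairness models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint fairness models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointfair)
```

## The problem

Risk prediction models trained on pooled data systematically under-serve
under-represented groups: either a single model compromises the minority
group's accuracy to fit the majority, or per-group models starve the small
group of samples. `jointfair` takes a third route: one sparse logistic
regression *per group*, with all groups estimated jointly under penalties
that (i) equalize predictive performance across groups and (ii) share
statistical strength between them.

## Model and penalties

For `K >= 2` groups with features `X_k` (n_k x p), binary outcomes `y_k`,
and group-specific coefficients `beta_k` with intercept `b_k`, the fit
minimizes the convex objective

> weighted deviance + fairness + similarity + sparsity

with the following terms.

**Weighted deviance.** `sum_k (1/n_k) * [negative Bernoulli log-likelihood
of group k]`. The `1/n_k` weights mean each *group*, not each observation,
contributes equally, so a 10x larger group cannot dominate the fit.
Computed with a softplus formulation that is exact and finite for linear
predictors beyond +-1000.

**Fairness (equalized odds surrogate).** Exact equalized odds would bound
the between-group differences of false-positive and false-negative rates,
which are non-convex in the coefficients. Because the sigmoid is
1/4-Lipschitz, the difference of *expected predicted probabilities* within
an outcome class is bounded by a quarter of the difference of *expected
linear predictors*; the penalty therefore shrinks, for every group pair
`j < k` and class `y`, the gap `|xbar_jy' btilde_j - xbar_ky' btilde_k|`
between class-conditional mean risk scores, where `xbar_ky` is the mean
(intercept-augmented) feature vector of the subjects in group `k` with
outcome `y`. This is why every group must contain both outcome classes.
Intercepts are part of the linear predictor and so *do* enter this
penalty.

**Similarity (fused lasso).** `lambda_Sim * sum_{j<k} ||beta_j -
beta_k||_1` pulls coefficients pairwise toward shared values — borrowing
strength without imposing a single model — and also resolves the
near-degeneracy of the likelihood when several coefficient combinations
fit almost equally well. Intercepts are excluded: groups may legitimately
differ in baseline risk.

**Sparsity.** Per-group L1 penalties `lambda_Sp^k * ||beta_k||_1` give
exact zeros and keep the problem well-posed when `n_k < p`. A scalar
`lambda_sp` is spread as `lambda_sp / sqrt(n_k)`, so smaller groups are
penalized relatively more heavily (their likelihood term is noisier); a
length-K vector overrides this tying. Intercepts are never penalized.

Both pairwise penalties enumerate **all** pairs `j < k`. For `K = 2` (the
benchmark setting) there is only one pair; for `K > 2` this matches the
penalty sums exactly rather than a chain of consecutive pairs.

## The solver

The fairness + similarity part equals `||D btilde||_1` for a sparse
stacked operator `D` with `M = (2 + p) * K(K-1)/2` rows, and has no
closed-form proximal operator. We follow the standard smoothing route:

1. **Nesterov smoothing.** `f_mu(b) = max{a' D b - (mu/2)||a||_2^2 :
   ||a||_inf <= 1}`, maximized in closed form by clipping `D b / mu` to
   [-1, 1]. The approximation satisfies `0 <= ||Db||_1 - f_mu(b) <=
   mu*M/2` and has a `||D||_2^2 / mu`-Lipschitz gradient `D' a*`.
2. **Accuracy-driven mu.** Given a target accuracy `delta` (solver option,
   default `1e-4`), `mu = delta / M` keeps the smoothing bias below
   `delta/2`. Smaller `delta` tightens the solution but inflates the
   Lipschitz constant — and hence shrinks the step size — proportionally to
   `1/delta`; this is the classic smoothing trade-off. For
   cross-validation and replicated benchmarks we use `delta = 1e-2`
   (prediction metrics are insensitive at that scale); for optimality
   checks against an independent convex solver, `delta = 1e-4`.
3. **FISTA with restart.** Gradient steps at fixed step `1/L`, `L = max_k
   ||Xtilde_k||_2^2 / (4 n_k) + ||D||_2^2 / mu` (the 1/4 bounds the
   sigmoid derivative; the likelihood Hessian is block-diagonal so the max
   over blocks suffices), a soft-threshold proximal step for the sparsity
   term (threshold `lambda_Sp^k / L`, zero on intercepts), and momentum
   extrapolation `theta_{t+1} = (1 + sqrt(1 + 4 theta_t^2))/2`. When the
   smoothed objective increases — momentum methods are not monotone — the
   momentum sequence is reset and a plain proximal step is taken from the
   previous iterate (adaptive restart; it preserves the `O(1/t^2)`
   guarantee while giving near-linear convergence on strongly-convex
   stretches).

Further numerical choices:

* **Initialization** at `beta = 0` with each intercept at the logit of its
  group's event rate: deterministic, scale-free, and exactly optimal in
  the fully-penalized limit.
* **Convergence** is declared when the smoothed objective's relative range
  over a 5-iteration window falls below `tol` (default `1e-6`); the
  single-iteration change oscillates under momentum. Hitting `max_iter`
  (default 5000) returns the result flagged `converged = FALSE`.
* **Spectral norms** come from power iteration on `D'D` with a fixed
  deterministic start vector (tolerance `1e-8`, cap `1e4` iterations); `D`
  is stored sparse above 1e5 entries and dense below.
* The **reported objective** is the exact non-smoothed one, so fits at
  different `delta` are comparable.
* Degenerate cases: `lambda_F = lambda_Sim = 0` makes `D` empty; smoothing
  is then inert (`mu = 1`) and the solver reduces to plain FISTA for
  lasso-logistic. A non-finite objective (pathological data) aborts with
  the iteration number.

## Comparator estimators

* `fit_separate()`: independent lasso-logistic per group (the same FISTA
  core without coupling).
* `fit_ignorant()`: one lasso-logistic on the pooled rows with `K - 1`
  reference-coded group indicators appended and penalized like ordinary
  features.
* `fit_sfm()`: a single shared coefficient vector under the fairness
  penalty. Its log-likelihood is the plain *sum* over groups — no `1/n_k`
  weights — matching the standard formulation of that comparator; a
  `weighted = TRUE` flag enables the group-weighted variant for ablation.
  Because its loss scales with total `n`, penalty grids for it should be
  scaled by `n` (as `run_experiment()` does).

Nesting identities used as correctness checks: the joint model at
`lambda_F = lambda_Sim = 0` equals the separate fits; the shared model at
`lambda_F = 0` equals a pooled lasso.

## Hyperparameter selection

`cv_select()` runs stratified K-fold cross-validation (folds stratified
jointly on group and outcome class, so every training split retains both
classes in every group — necessary for the fairness penalty and for
unbalanced designs). Criteria: harmonic or arithmetic mean of groupwise
AUCs, overall AUC, harmonic mean of groupwise Brier scores, or mean AUC
minus disparity. The default is the **harmonic mean of groupwise AUCs**:
it is dragged down by a single badly-served group, which is exactly the
sensitivity one wants with unbalanced groups. Ties break toward the
smallest `lambda_F`, then `lambda_Sim`, then `lambda_Sp` — the most
parsimonious fairness machinery. The generic default grid is `{0} union
logspace(1e-3, 10, 7)` per active penalty; the benchmark runner uses
compact grids (2-3 points per penalty around the scales that matter at
the benchmark's signal strength) to keep replicated experiments tractable.

## The synthetic benchmark generator

`scenario_spec()` / `generate_dataset()` emulate a two-group design:
iid standard-normal features; group-specific logistic models in which 40%
of features carry non-zero coefficients, all equal to 3; a controllable
fraction of the active coordinates shared between groups; group 1
over-represented (n = 500, target prevalence 50%) and group 2
under-represented (n = 200 by default, target prevalence 30%); test sets
of 1000 per group. Three presets vary, respectively, the shared fraction
(scenario 1), the minority sample size 50-300 (scenario 2), and the
dimension p (scenario 3, with a fixed-40 or proportional-40% active set).

Design choices within the generator:

* **Support placement is deterministic** (group 1 takes the first
  `n_nonzero` coordinates; group 2 shares the first `round(shared *
  n_nonzero)` and continues with fresh ones). Under exchangeable iid
  features this is statistically equivalent to random placement and keeps
  the ground truth stable across replicates.
* **Prevalence is the marginal event rate** `E[sigmoid(b + X beta)]` over
  the feature distribution, not the at-zero-covariates rate
  `sigmoid(b)`; groups are described by their observed event rates, which
  is the marginal quantity. Since `X beta ~ N(0, ||beta||^2)` exactly, the
  intercept is calibrated by root-finding on a fixed 2e5-draw Monte-Carlo
  sample; achieved prevalences are verified within +-1 percentage point on
  independent 1e5-sample draws.
* With 40 coefficients of size 3 the linear predictor has standard
  deviation ~19: the generator emulates a *strong-signal, saturated*
  regime in which likelihoods are flat in the large-coefficient direction
  and penalties bite early. Real clinical data are weaker-signalled,
  correlated, and mixed-type; passing benchmarks here demonstrates the
  estimators' comparative behaviour under the stated design, not
  performance on any real population.

`run_experiment()` wires it together: per replicate, generate ->
cross-validate -> refit -> evaluate (per-group AUC, Brier, FPR/FNR at the
0.5 cutoff, balanced accuracy, coefficient MSE excluding intercepts,
selection TPR/TNR, AUC disparity), then medians and IQRs across
replicates. Failed replicates are recorded and excluded.

## Problem sizes used in the shipped tests

The solver-optimality checks run ten random instances with `K = 2`,
`p <= 15`, total `n <= 200` against an independent minimizer (`nlminb` on
an epsilon-smoothed objective with continuation, a code path disjoint from
the package's solver), agreeing to `1e-4` relative objective. The
replicated benchmark checks use `p = 50` with 20 active coefficients
(the generator's 40% rule at that dimension), 10-12 replicates, 3 folds,
and compact grids — a deliberately desk-scale rendition of the full
design whose qualitative contrasts (minority-group AUC: joint >= separate
at n2 = 50; AUC disparity: joint <= pooled at 100% sharing) are the
quantities of interest.

## Known limitations

* Binary outcomes and linear logistic models only; no missing-data
  handling (validation rejects missing values) and group membership must
  be observed.
* The fairness penalty equalizes *mean* class-conditional scores — a
  first-order surrogate; it does not constrain higher moments of the score
  distributions.
* The smoothing step size degrades as `delta` shrinks (`L ~ 1/delta`);
  very tight tolerances on large problems are expensive. Warm starts
  across a penalty path are not implemented (each grid point is fit
  cold).
* L2 / elastic-net penalty variants and a group-lasso similarity term are
  out of scope, as are K > 2 benchmark presets (the estimators themselves
  accept any K >= 2).
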