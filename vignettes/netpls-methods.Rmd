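---
title: "Methods: net predictive association patterns by latent-variable projection"
author: "netpls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: net predictive association patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Cohort and omics studies routinely ask how an outcome $y$ (here, an
insulin-resistance proxy such as HOMA-IR) relates to a set of $M$
explanatory variables $\{x_1,\dots,x_M\}$ (adiposity measures, a
physical-activity intensity spectrum) in the presence of $K$ covariates
$\{z_1,\dots,z_K\}$ — confounders such as age and sex, or mediators such as
a serum lipoprotein profile. When the explanatory variables and especially
the covariates are strongly multicollinear (a 26-feature lipoprotein panel
is close to rank 3), the standard remedies fail: including everything in a
multiple linear regression is not interpretable when associations are not
independent, and residualising on the covariates by MLR is impossible when
the covariate block is rank deficient.

netpls addresses this with a single algebraic primitive used everywhere: the
four-step **projection algorithm**. Given a column-centred matrix $X_a$ and
a unit weight vector $w_a$:

1. choose $w_a$ with $\|w_a\| = 1$;
2. score $t_a = X_a w_a$;
3. loading $p_a = X_a^T t_a / (t_a^T t_a)$;
4. deflate $X_{a+1} = X_a - t_a p_a^T$.

Different weight criteria give different models:

* **PCA**: iterate steps 2–3 until the normalised loading reproduces the
  weight; components equal the truncated SVD.
* **PLS1**: $w_a = X_a^T y / \|X_a^T y\|$ on the deflated matrix. Only $X$
  is deflated; for a single outcome this is algebraically equivalent to
  schemes that also deflate $y$.
* **Target projection (TP)**: one pass with $w_{TP} = b/\|b\|$, where $b$
  is the regression vector of a fitted PLS model. The target score is
  collinear with the PLS fitted values, so this single component carries
  all the predictive outcome variance of the multi-component model; its
  loading $p_{TP}$ distributes that variance over the variables.
* **Covariate projection (CP)**: one pass on the augmented matrix
  $[y\;|\;Z\;|\;X]$ with an indicator weight on a covariate column; every
  column is residualised on the covariate and the covariate's own residual
  is exactly zero.

### Handling a multicollinear covariate block

A rank-deficient covariate block $Z$ cannot be projected out column by
column. Instead its association with the outcome is condensed into one
latent variable: fit a Monte-Carlo-validated PLS1 model of $y$ on $Z$,
target-project it, scale the target score to unit sample variance, and use
that score as a single covariate column in a CP. The net data
$y_{net} = y - \hat y_{cov}$, $X_{net} = X - \hat X_{cov}$ are then
modelled by a second validated PLS1 + TP, giving the net predictive
association pattern $b_{net}$, $t_{net,TP}$, $p_{net,TP}$.

### The total model and its variance partition

After $n_{CP}$ covariate projections and the net target projection,

$$X = \sum_{a=1}^{n_{CP}} \hat X_{cov,a} + t_{net,TP}\,p_{net,TP}^T + E_{X,TP},$$

and analogously for $y$. All parts are mutually orthogonal, so for every
variable the fractions of its **original** (pre-adjustment) variance
attributed to each projection, to the net component, and to the residual
sum to one. These fractions are the variance plot; aggregated over blocks
(outcome, adiposity, activity spectrum) they give the stagewise
remaining/explained variance table produced by `summary()`.

Orthogonality requires one care point that the package handles internally:
a block's target score is computed from the (by default unadjusted) block
columns, so before its CP it is residualised on the scores of all previous
projections (Gram–Schmidt). This is equivalent to the score column having
sat in the augmented matrix from the first projection onward. The net data
are unaffected — the projection span is identical — but the per-projection
variance attribution depends on projection order whenever covariates are
correlated, which is a property of stepwise adjustment itself, not of the
implementation. The final net data do not depend on the order.

### Variable importance

With the target score oriented towards the predicted outcome, the
**selectivity fraction** of variable $i$ is

$$SF_i = \mathrm{sign}(p_{i,TP})\,\|t_{TP} p_{i,TP}\|^2 / \|x_i\|^2 \in [-1, 1],$$

the signed share of the variable's total variance captured by the
predictive component. The **selectivity ratio** divides by the residual
variance $\|e_{i,TP}\|^2$ instead ($SR_i = |SF_i|/(1-|SF_i|)$), is
unbounded, and is capped at $10^6$ (with a flag) for variables fully
captured by the component. Confidence limits for $SF$ come from refitting
the PLS + TP model (component count held fixed) on repeated random
calibration halves and taking the empirical 2.5/50/97.5 percentiles of the
per-variable $SF$ distribution. The component-selection literature
sometimes attributes such limits to the prediction-error distribution;
prediction errors cannot yield per-variable limits, so the resampled-model
$SF$ distribution is the mechanism implemented here, and it is the one
`mc_importance()` documents.

## Monte Carlo selection of the number of components

`mc_validate()` implements repeated Monte Carlo resampling with three user
inputs: the number of repetitions (default 1000), the maximum component
count (default 6), and the acceptance threshold (default 0.5). Each
repetition draws `floor(split * N)` subjects (default half) without
replacement as calibration set, centres and scales both halves with
calibration statistics only (no information leakage), fits PLS1 with
0..A_max components, and records the held-out RMSEP (or MAE). The
0-component reference model predicts the calibration mean, which anchors
the "one component less" comparison at $A = 1$; its median error is the
held-out outcome SD.

Selection starts at the component count with the smallest median error
(smallest count on ties; ties are declared at a relative tolerance of
1e-8 of the 0-component median so that float-level noise on an exact fit
cannot inflate the count). A candidate $A$ is accepted if the fraction of
its errors strictly exceeding the median error of the $(A-1)$-component
model is below the threshold; otherwise $A$ is decremented and the
comparison repeated, possibly down to 0. Lower thresholds are more
conservative, and selection is monotone in the threshold. Splits are not
stratified. All resampling is driven by the seed recorded in the
configuration; in `netpls()` every stage derives its own seed from the
master seed by fixed offsets, so stages are individually reproducible.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_rep` | 1000 | Monte Carlo repetitions; medians stabilise to ~2% by 1000 |
| `A_max` | 6 | largest component count assessed |
| `threshold` | 0.5 | exceedance-fraction acceptance level; below 0.5 protects against overfitting, lower is stricter |
| `split` | 0.5 | calibration fraction per repetition |
| `cost` | RMSEP | held-out cost; MAE available for heavy-tailed outcomes |
| `log_columns` | none | variables to natural-log before centring (binary/age-like variables excluded) |
| `standardize` | TRUE | unit sample variance (N−1 denominator) for all retained columns |

Two conventions are fixed for reproducibility rather than substance: the
natural (not base-10) logarithm, and standardisation of *every* retained
column including 0/1-coded binaries — a binary covariate's CP is
scale-invariant, so this affects only reported correlation/score scales,
not residuals. Variance bookkeeping always uses the variance recorded
immediately before scaling as the denominator, and net matrices are never
re-standardised between projection steps, so all percentages remain
fractions of the original variance.

## Numerical choices

* PCA power iteration runs on the $V \times V$ cross-product matrix
  (identical fixed point, cheap iterations), tolerance 1e-12 on the weight
  change, at most 10000 iterations, deterministic start at the
  largest-variance column; components are sign-fixed so the
  largest-magnitude loading entry is positive. Numerically equal
  successive eigenvalues are flagged as a degenerate subspace.
* The PLS regression vector is recovered as $b = W (P^T W)^{-1} q$ by a
  triangular solve; $P^T W$ is unit upper triangular in this deflation
  scheme.
* A covariate whose residual sum of squares falls below 1e-12 of the mean
  column sum of squares is refused (hard error), as is re-projection of an
  exhausted covariate.
* If $X_a^T y$ vanishes before the requested number of components, the
  model is truncated with a warning (error if no component at all can be
  extracted).
* Missing values are a hard error for all modelling functions; import
  only reports them.
* Quantiles are empirical type-7; the SR cap is $10^6$.

## The synthetic cohort generator

`simulate_cohort()` draws from a linear Gaussian structural model chosen
to emulate a school-cohort dataset of 836 children: a binary sex indicator
(Bernoulli 0.5) and a narrow age distribution (10.22 ± 0.29 years) as
confounders; an adiposity factor measured by three strongly correlated
variables (pairwise r ≈ 0.7–0.85, with a sex effect on skinfold); a
23-variable activity spectrum with smooth factor loadings peaking at
moderate intensities, a sex effect growing with intensity, and AR(1)
serial noise (lag-1 correlation 0.85) along the intensity index; and a
26-feature mediator block generated from 3 latent factors driven by the
adiposity and activity factors and sex, optionally with exactly duplicated
columns to force rank deficiency. Marginals are log-normal by default, so
the standard preprocessing (log, centre, scale) returns them to the linear
scale. The outcome coefficients were fixed once, against the analytic
population covariance, so that the population values match the magnitudes
reported for comparable cohorts: score–outcome correlation ≈ 0.50,
unadjusted explained outcome variance ≈ 30%, net explained ≈ 14%,
remaining outcome variance after full adjustment ≈ 74%.

Because every observed variable is an explicit linear combination of
independent unit-variance latents, the population correlation matrix is
exact, and `population_truth()` derives closed-form references: the
mediator score direction (population best linear predictor of the outcome
from the block), the net pattern (the net covariance
$\mathrm{Cov}(x_{net}, y_{net})$, which is what the net TP loading
estimates), and the explained-variance fractions before/after adjustment.
`recovery_report()` compares a fit against these.

What the generator does **not** emulate: accelerometer count
distributions, lipoprotein physiology beyond the covariance structure,
nonlinearity, interactions, heteroscedasticity, or missingness. Passing
recovery tests therefore demonstrate correctness of the estimator under
the linear model it assumes, not robustness to real-data pathologies.

## Design choices on genuinely open points

* **Block score from unadjusted data.** The block compression can be fit
  on unadjusted data (default, `compress_on = "unadjusted"`) or on the
  data as adjusted so far. The default matches the reference workflow of
  fitting the mediator–outcome model on raw standardised data and then
  projecting stepwise (confounders first, then the score); both routes are
  supported because the distinction matters only when confounders and the
  block overlap strongly.
* **Univariate covariates before blocks** in the default projection
  order; overridable via `order`.
* **Strict exceedance.** "Exceeds the median" is a strict inequality;
  ties count as not exceeding. The downward walk re-tests each
  $(a, a-1)$ pair until acceptance or $a = 0$.
* **Sign conventions.** $t_{TP}$ is oriented so its regression on the
  outcome is positive; $SF$ takes its sign from $p_{i,TP}$. This makes a
  positive $SF$ read as "associated with higher outcome".

## Problem sizes used by the test-suite

The package's own checks run the Monte Carlo machinery at reduced sizes
chosen to keep the full suite fast while leaving selection behaviour
intact: 80–200 repetitions for unit tests, 120 repetitions with 20
replicate cohorts of N = 800 for the parameter-recovery checks, and 150
repetitions for the null/one-factor selection frequency checks (N = 200).
The reproduction scripts use the full 1000 repetitions.

## Known limitations

* One outcome at a time (PLS1); no PLS2.
* Complete-case analysis only; impute beforehand if needed.
* Mediation is quantified purely as explained-variance change. No
  indirect-effect confidence intervals and no causal identification
  assumptions are provided; "mediated share" is descriptive.
* Stepwise attribution of shared covariate variance is order-dependent
  for correlated covariates (the net data are not); interpret the ledger
  with the chosen order in mind.
* The residual matrix $E_{X,TP}$ can be exported for further exploration
  (e.g. PCA), but no built-in analysis of it is performed.
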