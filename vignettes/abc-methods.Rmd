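---
title: "Abundance-based constraints for race-modified regression: models, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abundance-based constraints: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abcreg)
```

## The model and its identification problem

`abcreg` fits Gaussian linear models in which a continuous covariate's
slope may differ by the level of a categorical covariate,

$$\mu(x, r) = \alpha_0 + \sum_{j=1}^p \alpha_j x_j + \beta_r +
  \sum_j \gamma_{r,j} x_j,$$

with the natural generalization to several categorical variables (each
contributing a $\beta$ block, and optionally $\gamma$ blocks for the
covariates it modifies). Because each block of level coefficients is only
determined up to an additive shift, one linear constraint per block is
needed. The package implements four identifications behind a single
interface:

* **ABC** (abundance-based): $\sum_r \hat\pi_r \beta_r = 0$ and
  $\sum_r \hat\pi_r \gamma_{r,j} = 0$, with $\hat\pi_r$ the group
  proportions. Main effects become proportion-weighted averages of the
  group-specific effects.
* **RGE** (reference-group encoding): $\beta_1 = \gamma_{1,j} = 0$ for a
  declared reference level. Main effects are reference-group-specific.
* **STZ** (sum-to-zero): unweighted block sums vanish; equivalent to ABC
  when all groups are equally abundant.
* **OVER**: no constraints. The least-squares problem has no unique
  solution, so this scheme is admitted only for penalized estimation.

All four produce the same fitted surface for OLS (identical fitted values
and group-specific slopes); they differ in *which* linear functionals of
that surface are called "main effects", and — importantly — in how
penalized estimators shrink.

Group proportions default to the sample frequencies; externally known
population shares can be supplied instead. With multiple categorical
variables the constraints use per-variable marginal proportions, which is
equivalent to the joint-expectation formulation of the constraint; a
supplied joint table is marginalized.

## Estimation

The constrained least-squares problem is reduced to an unconstrained one
by a null-space reparametrization: writing the QR decomposition
$C^\top = QR$ and letting $Q_{\mathrm{null}}$ be the trailing $P - m$
columns of $Q$, every $\theta = Q_{\mathrm{null}}\zeta$ satisfies
$C\theta = 0$, so OLS runs on $Z = X Q_{\mathrm{null}}$ and
$\hat\theta = Q_{\mathrm{null}}\hat\zeta$. Under i.i.d. Gaussian errors the
estimator is exactly
$\hat\theta \sim N(\theta,\ \sigma^2 Q_{\mathrm{null}}
 (Z^\top Z)^{-1} Q_{\mathrm{null}}^\top)$,
which the package uses for finite-sample inference. Numerical contracts:
$\|CQ_{\mathrm{null}}\|_\infty < 10^{-10}$,
$\|Q_{\mathrm{null}}^\top Q_{\mathrm{null}} - I\|_\infty < 10^{-10}$, and
all downstream estimates are invariant (to $10^{-8}$) to rotation of the
null-space basis, which the test suite verifies directly.

Design choices the field leaves open, and what this package does:

* **Residual degrees of freedom** are $n - (P - m)$: the reduced
  parametrization has $P - m$ free coordinates.
* **Inference reference distribution** is the $t$ with those df (not the
  normal), recovering the asymptotic normal for large samples. Default
  confidence level 95%, two-sided p-values, no multiplicity adjustment by
  default (an optional `p_adjust` argument exposes `p.adjust` methods).
* **Rank deficiency is an error**, not silent column dropping: equitable
  reporting requires every declared level to be estimable, so the fit
  names the offending columns instead of quietly omitting a group. A
  level observed only once makes its indicator and interaction columns
  collinear and is reported the same way.
* **Missing data**: rows with missing outcome or used covariates are
  dropped with a reported count; no imputation.
* **Centering/scaling** (`center_scale = TRUE`) standardizes continuous
  covariates by their mean and population-style standard deviation
  (divisor $n$), consistent with the scaled-variance convention used in
  the invariance condition below. Coefficients are reported on the
  transformed scale.

## Estimation invariance and its diagnostic

For a single modified covariate, the ABC main-effect estimate from the
modified model equals the main-only estimate exactly whenever the scaled
within-group sample variances
$\hat\sigma^2_x[r] = s_r^2/n_r - \bar x_r^2$ agree across groups — and is
empirically near-invariant under mild violations. No such property holds
for RGE or STZ. `variance_diagnostic()` tabulates the per-group scaled
variances and flags departures (default: ratio to the largest group
outside $[2/3, 3/2]$); `invariance_report()` fits both models and reports
the paired estimates and standard errors. For several covariates the
equal-variance condition has per-covariate analogues only; the package
checks the $p = 1$ condition per covariate and otherwise reports the
empirical comparison.

## Penalized estimation

The penalty is $\lambda \sum_j \omega_j |\theta_j|^\delta$ on the
*original* coefficients, with $\omega_j$ the population-style standard
deviation of design column $j$ and $\omega = 1$ for the intercept. The
weights matter under ABCs: a low-abundance group's indicator column has
small variance but its coefficients are correspondingly large, and the
standardized penalty avoids overpenalizing such groups. Because the
stated intercept weight of 1 does penalize the intercept — an unusual
choice — the CLI exposes `--unpenalized-intercept`.

Ridge ($\delta = 2$) has the closed form
$\hat\theta(\lambda) = Q_{\mathrm{null}}(Z^\top Z + \lambda D^\top D)^{-1}
Z^\top y$ with $D = \mathrm{diag}(\omega^{1/2}) Q_{\mathrm{null}}$. The
lasso ($\delta = 1$) is a generalized lasso in the reduced coordinates
(the penalty acts on $\mathrm{diag}(\omega) Q_{\mathrm{null}} \zeta$),
solved by scaled ADMM with residual balancing (absolute tolerance
$10^{-8}$, relative $10^{-6}$, cap 50,000 iterations) and warm starts down
the grid, followed by a KKT "polish": the splitting variable's exact zero
pattern and active signs define an equality-constrained quadratic program
whose solution is kept when it is sign-consistent and does not increase
the objective. Polishing yields exact zeros, so ABC sparsity semantics are
exact: when a whole $\gamma$ block is zeroed, every group slope collapses
to the *group-averaged* slope $\hat\alpha_j$ — not to a reference group's
slope as under RGE.

The default grid is 100 log-spaced values from
$\lambda_{\max} = \max_j 2|x_j^\top y|/\omega_j$ (the zero-solution
optimality certificate for the squared-error loss written without the
$1/2$ factor) down to $10^{-4}\lambda_{\max}$. At or above
$\lambda_{\max}$ the exact zero solution is returned without iteration.
Cross-validation uses mean squared prediction error over $K$ folds
stratified by the first categorical variable (to reduce level dropout; a
fold that still loses a level is redrawn once, then errors), and reports
both the error-minimizing $\lambda$ and the one-standard-error choice.
The overparametrized scheme runs through the same machinery with the
identity basis; $\lambda = 0$ is rejected as non-unique.

## Scheme conversion and equitable reporting

Every identification describes the same surface through the invariant
per-group intercepts $\mu(0, r) = \alpha_0 + \beta_r$ and slopes
$\mu'_j(r) = \alpha_j + \gamma_{r,j}$. `convert_scheme()` recovers these
and re-centers per the target scheme — proportion-weighted means (ABC),
unweighted means (STZ), or reference subtraction (RGE) — an exact linear
map that never touches data, so round trips are identities to machine
precision. Published tables are usable directly: omitted RGE reference
rows are imputed as exact zeros, and conversions of 3-decimal printed
inputs carry an expected ±0.002 rounding footprint (the package's shipped
worked example reproduces a published ABC column to within that
tolerance; the original was computed from raw data, not from the rounded
RGE column). Converted intercept interpretations as marginal expectations
presuppose covariates centered at fit time. Standard-error conversion for
external tables is out of scope — it requires the full covariance, which
publications rarely print — and penalized estimates are not related by a
linear map across schemes, so conversion applies to OLS coefficients
only.

`equitable_report()` renders TSV or Markdown tables listing the intercept,
every main effect, **every** categorical level, and every interaction
level; an RGE table names its reference group explicitly and shows the
constrained-to-zero rows rather than hiding them. Rendering rounds to 3
decimals; objects keep full precision.

## The simulation designs

Two generators ship as first-class, tested code.

**Misspecified-model benchmark.** Data come from a Gaussian *main-only*
model with $p = 10$ covariates and one 4-level categorical variable:
six covariates i.i.d. $N(0,1)$, four ($X_4, X_5, X_9, X_{10}$) with
group-dependent mean equal to the group index; $\alpha_0 = 1$,
$\alpha_{1..5} = 1$, $\alpha_{6..10} = 0$, $\beta = (0, 1, 0, -1)$, group
proportions symmetric $(0.15, 0.35, 0.15, 0.35)$ or uniform. The truth
satisfies both RGE ($\beta_1 = 0$) and ABC
($\sum_r \pi_r \beta_r = 0$) so no scheme is advantaged by construction.
The fitted models include all 30 extraneous interaction columns (55
design columns, 44 identifiable parameters). The noise variance equals
the *analytic population* variance of the signal (signal-to-noise ratio
one); an empirical per-dataset variant is available since the convention
is a genuine choice. Datasets are redrawn wholesale (up to 1000 times)
until every level has at least $p + 1$ observations, the minimum for OLS
with a full interaction block. RMSEs against the truth are recorded for
coefficients, group-specific slopes, and model expectations, with ridge
and lasso tuned per replicate by the one-standard-error rule.

**Invariance experiment.** Groups A–D with probabilities
$(0.55, 0.20, 0.10, 0.15)$; $x \mid r$ is $5 + N(0,1)$,
$\sqrt{12}\,U(0,1)$, $5 + t_4/\sqrt2$, or $\mathrm{Gamma}(1,1)$ — each
with population variance one, so sampling noise provides only a *mild*
deviation from the equal-variance condition. Two readings of the stated
group distributions required a decision: "$12\,U(0,1)$" is taken as
$\sqrt{12}\,U(0,1)$ (the unique unit-variance reading), and the raw
$t_4$ (variance 2) is scaled by $1/\sqrt2$ by default, with
`scale_t4 = FALSE` for the literal unscaled draw. The response mean is
$1 + x + \gamma x\,1(r{=}A) - \gamma x\,1(r{=}B)$ with unscaled $t_4$
errors and $\gamma \in \{0, 0.5, 1.5\}$; the generator intentionally
satisfies neither ABC nor Gaussian-error assumptions. Each replicate is
fit main-only and modified under ABC, RGE (reference A), and STZ, and the
paired main-effect estimates are summarized by median absolute
discrepancy.

Seeding: a master seed spawns fixed per-replicate substreams, so
replicate $k$ is bit-identical regardless of the total replicate count,
and every randomized routine (fold assignment included) records its seed.

## What the generators do and do not emulate

The generators reproduce the *structural* challenges the method
addresses — group-dependent covariate distributions, unbalanced
abundances, extraneous interactions, heavy-tailed errors — but not the
features of administrative cohort data: spatial and serial correlation,
measurement error in exposures, informative missingness, or the scale of
real linked records. Passing benchmarks therefore demonstrate correctness
of the estimators and the claimed orderings between schemes under
controlled conditions, not real-data effect sizes. The NC education
analysis whose published coefficient table ships with the package is
privacy-restricted microdata; only the printed coefficients (and their
conversion arithmetic) are reproducible here.

## Problem sizes used in the test suite

The shipped tests run the invariance experiment at 100 replicates
($n = 500$, $\gamma \in \{0.5, 1.5\}$) and the benchmark at 50 replicates
($n = 250$, symmetric proportions, 50-value penalty grid, 5-fold CV),
with the sample-size scaling check at $n = 2500$ — sizes chosen so the
orderings of interest (ABC's smaller discrepancy and RMSE) are stable
across seeds while the full suite stays interactive. The reference
experiment sizes (500 replicates, $n$ up to 10,000) are available through
the same configuration objects.

## Known limitations

* Categorical-by-categorical interactions, ordered (Helmert) codings, and
  non-Gaussian GLMs are out of scope.
* No robust/sandwich or weighted-least-squares variants.
* The lasso path is a fixed-grid solver, not an exact piecewise-linear
  path algorithm; accuracy is contractually tied to the ADMM tolerances
  plus KKT polishing and is oracle-checked in the tests.
* Back-transformation of coefficients fitted on standardized covariates
  is left to the user.
* The overparametrized scheme has no quantitative accuracy contract
  beyond solver convergence; its paths can behave erratically, which is
  part of the argument for constraints.
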