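# abcreg

Linear regression with categorical covariates and categorical-by-continuous
effect modifiers under **abundance-based constraints (ABCs)**, with
comparator identifications (reference-group encoding, sum-to-zero,
overparametrized), constrained OLS with finite-sample inference, weighted
ridge/lasso regularization with cross-validated tuning, and exact
conversion of published coefficient tables between identification schemes.

## The problem

Regression analyses in epidemiology and the social sciences routinely
include a categorical covariate such as race together with race-by-exposure
interactions ("race-modified models"):

    E(Y | x, r) = alpha_0 + sum_j alpha_j x_j + beta_r + sum_j gamma_{r,j} x_j

The coefficients are not identifiable without a constraint on each `beta`
block and each `gamma` block. The default choice, reference-group encoding
(RGE), pins one group's coefficients to zero — so the reported "main
effects" are silently specific to the reference group (typically the
majority group), and regularized estimation shrinks every group toward that
reference. ABCs instead require each block to average to zero under the
group proportions `pi_r`:

    sum_r pi_r beta_r = 0,   sum_r pi_r gamma_{r,j} = 0  for every j

so that `alpha_j` is the proportion-weighted average of the group-specific
slopes `mu'_j(r) = alpha_j + gamma_{r,j}`, every group receives a reported
coefficient, and — remarkably — the main-effect estimates are essentially
unchanged when the modifier terms are added to the model (exactly unchanged
when the within-group scaled variances of the covariate are equal).

Estimation reduces the linearly constrained least-squares problem to an
unconstrained one via the QR decomposition of the transposed constraint
matrix: with `C' = QR` and `Q_null` the trailing columns of `Q`, any
`theta = Q_null zeta` satisfies `C theta = 0`, so OLS runs on the reduced
design `Z = X Q_null`. The same reparametrization gives closed-form
weighted ridge and a generalized-lasso form (solved by ADMM with KKT
polishing) for weighted ell-1 penalties on the original coefficients.

## Worked example

Published regression output for the effect of racial isolation (RI) on
4th-grade reading scores in North Carolina was reported under RGE with
reference NH White. Converting it to ABCs with the cohort race proportions
(58% NH White, 36% NH Black, 6% Hispanic):

```r
library(abcreg)
pub  <- nc_ri_published()        # printed RGE coefficient table
conv <- convert_scheme(pub$rge, "ABC")
equitable_report(conv)
```

```
Variable        Estimate
(Intercept)     0.014
RI              -0.031
race
  NHW   0.253
  NHB   -0.417
  Hisp  0.062
RI x race
  RI:NHW        0.018
  RI:NHB        -0.039
  RI:Hisp       0.052
```

Under RGE the printed "RI effect" (−0.013, n.s.) is the NH White-specific
slope. Under ABCs the RI main effect (−0.031) is the race-averaged slope,
and the group-specific slope for NH Black students is
`alpha_RI + gamma_RI:NHB = -0.031 + -0.039 = -0.070` — more than double the
average effect. Every race group gets a reported coefficient; no group's
effects masquerade as global ones.

Fitting from data works the same way:

```r
sp  <- model_spec("y", "RI", list(race = c("NHW", "NHB", "Hisp")),
                  modifiers = "all", scheme = "ABC", center_scale = TRUE)
fit <- fit_ols(constrained_design(sp, my_data))
coefficient_inference(fit)   # every level, with SE / t / p / CI
group_slopes(fit)            # alpha_j + gamma_{r,j} per group, with CIs
```

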