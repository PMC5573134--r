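# ralasso

Robust adaptive lasso for sparse linear regression with outlying or
heavy-tailed responses.

## What problem this solves

High-dimensional regression workflows — biomarker selection, gene
expression modelling, epidemiological risk models — routinely rely on
penalised least squares (lasso, adaptive lasso, elastic net) to pick a
sparse set of predictors. Squared-error loss, however, lets a few gross
response outliers corrupt both the coefficients and the selected support.
`ralasso` implements a weighted-likelihood adaptive lasso: every
observation gets a weight in [0, 1] from a Pearson residual comparing the
empirical distribution of (standardized) residuals against a reference
model distribution, and the penalised fit is run on the weighted
likelihood.

The residual function compares tail masses,

    tau(y) = F_n(y)/F_theta(y) - 1        if F_theta(y) <= q
           = 0                            if q < F_theta(y) < 1 - q
           = S_n(y)/S_theta(y) - 1        if F_theta(y) >= 1 - q

and the weight is `w = exp(-alpha * tau^2)`, so observations consistent
with the model keep weight ~1 and gross outliers are smoothly annihilated.
With weights fixed, the estimator minimises

    (1/2n) sum_i w_i (y_i - b0 - x_i' beta)^2  +  lambda * sum_j |gamma_j| / max(|beta_init_j|, 1e-8)

by cyclic coordinate descent over a 100-point regularisation path
(`gamma_j` is the coefficient on the standardized predictor scale), with
10-fold cross-validation of the weighted held-out error selecting
`lambda`. The initial estimator is a Tukey bisquare M-estimator (with a
least-trimmed-squares warm start) when n > p, and cross-validated ridge
when p >= n.

## Worked example

Thirty percent of the responses below are shifted by -10: a classic gross
contamination. The ordinary adaptive lasso breaks; the robust fit does
not.

```r
library(ralasso)
spec <- scenario_spec("I", n = 100, delta = 0.3, r = 0.5,
                      test_contaminated = FALSE)
dat <- generate_scenario_data(spec, seed = 7)   # truth: 3, 1.5, 0, 0, 2, 0, 0, 0

fit <- fit_ral(dat$X, dat$y, seed = 1)
print(fit)
#> ral fit: n = 100, p = 8
#>   lambda = 0.025838 (path of 100), nonzero coefficients: 3
#>   observation weights: min 0, 34 below 0.5
round(coef(fit), 3)
#> (Intercept)          V1          V2          V3          V4          V5
#>       0.019       2.959       1.477       0.000       0.000       1.854
#>          V6          V7          V8
#>       0.000       0.000       0.000

alasso <- fit_baseline(dat$X, dat$y, "adaptive_lasso", seed = 1)
round(alasso$beta, 3)
#>     V1     V2     V3     V4     V5     V6     V7     V8
#>  2.657  1.905 -0.732  0.822  1.943 -0.490  0.262 -0.129

mean((dat$y_test - predict(fit, dat$X_test))^2)     # robust:      1.08
mean((dat$y_test - predict(alasso, dat$X_test))^2)  # non-robust: 12.90
```

The robust fit recovers the true support exactly (34 contaminated
observations get weight below 0.5, the gross ones exactly 0) and its
clean-test prediction error sits near the noise floor of 1, an order of
magnitude below the unweighted adaptive lasso whose intercept absorbed the
contamination shift.

Replicated comparisons with the study engine:

```r
st <- run_study(spec, c("ral", "adaptive_lasso"), n_reps = 50,
                B = 500, seed = 1)
print(st)
#> Scenario I, n = 100, p = 8, r = 0.5, delta = 0.3, 50 reps
#>          method med_pmse boot_se    C    I
#>             ral    1.081 0.01097 4.32 0.00
#>  adaptive_lasso   10.620 0.65268 4.46 0.02
```

`med_pmse` is the median test-set mean squared prediction error over
replications, `boot_se` its bootstrap standard error (B = 500), and C / I
the average counts of truly-zero coefficients correctly zeroed (of 5) and
truly-nonzero coefficients incorrectly zeroed (of 3).

## Command line

```sh
exec/ral weights --input values.csv --q 0.25 --alpha 0.05 --out weights.csv
exec/ral fit --x X.csv --y y.csv --seed 1 --out model.json --coef-out coef.csv
exec/ral simulate --scenario 1 --delta 0.3 --r 0.5 --reps 200 --seed 1 --out table.csv
exec/ral fixture --kind prostate_like --seed 1 --out prostate.csv
exec/ral casestudy --dataset prostate --file prostate.csv --out case.csv
```

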