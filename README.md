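# regplsc

Consistent partial least squares path modeling (PLSc) with an optional
ridge-regularized estimation step (RegPLSc), plus a Monte Carlo harness for
evaluating parameter recovery, statistical power and type-I error of both
estimators under multicollinearity.

## The problem

Variance-based structural equation modeling represents each latent variable
as a weighted composite of its observed indicators. When the indicators
follow a common factor model, composite scores carry measurement error, and
correlations between composites *underestimate* the latent correlations.
Consistent PLS corrects this attenuation: after estimating Mode A indicator
weights `w` by the iterative PLS algorithm, each block's reliability is
estimated by the consistent coefficient

    rho_A = (w'w)^2 * w'(S - diag(S))w / w'(ww' - diag(ww'))w,

every composite correlation is divided by the square root of the product of
the two reliabilities, and each structural equation is estimated by ordinary
least squares on the disattenuated correlations:

    beta_hat = Rx^{-1} r_xy.

Disattenuation inflates correlations between *predictors* too, so PLSc
frequently faces near-singular `Rx` — unstable coefficients, inflated
standard errors, lost power. RegPLSc replaces the OLS step with a ridge
solve,

    beta_hat(lambda) = (Rx + lambda I)^{-1} r_xy,   lambda >= 0,

with `lambda` chosen per structural equation by K-fold cross-validation on
the disattenuated scale. `lambda = 0` recovers ordinary PLSc exactly.
Inference for both estimators uses nonparametric bootstrap percentile
confidence intervals; a path is declared significant when its interval
excludes zero.

## Worked example

```r
library(regplsc)

# six latent variables, four reflective indicators each; xi1-xi2 correlated 0.8
pop <- build_population(list(N = 100, phi = 0.8, reliability = 0.8, r2 = 0.25))
X <- generate_sample(pop, N = 100, seed = 11)

fit <- plsc_fit(X, pop$model, method = "regplsc", seed = 1)
print(fit)
```

```
Consistent PLS fit (method: regplsc)
Path coefficients:
gamma11 gamma12 gamma21 gamma22 gamma23  beta31  beta32 
 0.1744  0.2229  0.4193  0.0490  0.3395  0.3803  0.1830 
lambda per equation: eta1 = 0.3857, eta2 = 0.1083, eta3 = 0.2807 
rho_A: xi1 = 0.798, xi2 = 0.765, xi3 = 0.844, eta1 = 0.802, eta2 = 0.859, eta3 = 0.829
```

The coefficients are standardized structural paths (population values here:
0.281, 0.246, 0.354, 0, 0.354, 0.391, 0.311); `lambda` is the ridge shrinkage
cross-validation chose per endogenous equation — largest for `eta1`, whose
two predictors are the collinear pair — and `rho_A` are the estimated
composite reliabilities used for disattenuation (population value 0.8).
Bootstrap inference:

```r
boot <- plsc_bootstrap(X, pop$model, method = "regplsc", B = 500, seed = 2)
print(boot)
```

A scaled-down Monte Carlo replication of the full 48-cell design:

```r
study <- run_study(enumerate_cells(), reps = 100, B = 0, seed = 1)
print(study)
```

```
Monte Carlo study: 48 cells x 100 replications (B = 0)
Grand-mean MAD per method:
  method       mad
    plsc 0.1642375
 regplsc 0.1326223
```

The mean absolute difference (MAD) between estimated and true standardized
coefficients, averaged over all cells and replications, is smaller for the
regularized estimator; the gap widens with the collinearity level (see
`aggregate(mad ~ method + phi, study$reps, mean)`).

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/regplsc.R", package = "regplsc"))')
Rscript $CLI fit --data data.csv --spec model.json --method regplsc --out results/
Rscript $CLI simulate --reps 100 --bootstrap 0 --seed 1 --out results/
Rscript $CLI report --out results/
```

`fit` writes per-path coefficients with bootstrap intervals, reliabilities,
the consistent correlation matrix and a JSON run-metadata file; `simulate`
writes per-cell results, rejection-rate and per-replication tables; `report`
summarizes result files without recomputation.

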