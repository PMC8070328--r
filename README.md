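# bspmm

Bayesian LASSO- and ridge-penalized spline smoothing for binary outcomes.

## What this solves

Epidemiological dose-response questions — how does the risk of a binary
outcome (disease yes/no) change with a continuous exposure such as pack
years of smoking, age, or BMI? — are routinely distorted by forcing the
relationship to be linear or by categorizing the exposure. `bspmm` fits the
logistic **semiparametric mixed model** (SPMM)

```
logit P(Y_i = 1 | x_i) = m(x_i),
m(x) = b0 + b1 x + sum_k u_k b_k(x),
```

where the `b_k` are low-rank thin-plate spline basis functions at K knots
and the knot coefficients `u_k` enter as random effects. Their prior is the
penalty:

* `u_k ~ Laplace(0, tau)` — an L1 (**LASSO**) penalty with smoothing
  parameter `lambda = 1/tau`;
* `u_k ~ N(0, sigma^2)` — the classical L2 (**ridge**) penalty with
  `lambda = 1/(2 sigma^2)`.

The scale (tau or sigma) is a variance component with a Uniform(0, 100) or
half-Cauchy(25) hyperprior, so the amount of smoothing is estimated from
the data. Inference is fully Bayesian via a blocked Gibbs sampler
(Pólya-Gamma logistic data augmentation + exponential scale mixture for the
Laplace prior + exact precision-scale updates for the variance components),
implemented in C++. Additive models with several smoothers and binary fixed
effects (odds ratios) are supported, as are truncated quadratic and natural
cubic bases for sensitivity analyses.

The package also ships the complete simulation machinery used to compare
the two penalties: three calibrated test shapes (linear, concave, double
hump), a seeded generator with prevalence 1/2 and success probabilities in
[0.02, 0.98], and the MASE / MACP / MACL performance metrics over the full
curve and its 10% boundary strips.

## Worked example

Simulate one benchmark dataset (concave truth, n = 500) and fit the
LASSO-penalized model with 7 knots under the reduced MCMC protocol:

```r
library(bspmm)

fn   <- calibrate_function("concave")
dat  <- generate_dataset(fn, n = 500, seed = 42)
spec <- spmm_spec(penalty = "lasso", basis = basis_spec("lrtp", K = 7))
fit  <- fit_spmm(dat, spec, mcmc_config(n_iter = 10000, burn_in = 1000,
                                        thin = 10, seed = 7))
fit
#> Penalized-spline logistic mixed model (lasso penalty, lrtp basis)
#> n = 500  K = 7  chains = 1  retained draws = 900
#>
#>    parameter   median  lower upper
#>  1 (Intercept)   3.41  -7.18 16.1
#>  2 x1           -2.51 -23.5  15.3
#>  3 u1           -5.08 -12.9   1.71
#>  ...
#> 10 gamma1        6.60   2.18 27.0
```

The individual spline coefficients are not interpretable one by one (the
basis columns overlap); the object of interest is the fitted logit curve
`m(x)` with its pointwise 95% credible band, available at the data points
in `fit$curve_summary` or on any grid via `credible_band(fit, grid)`.
Because the data are synthetic we can score the fit against the truth:

```r
ase(fit$curve_summary$median, dat$m_true)
#> [1] 0.0282
acp_acl(dat$m_true, fit$curve_summary$lower, fit$curve_summary$upper)
#>   acp   acl
#> 1.000 1.297
```

— an average squared error of 0.028 on the logit scale, with the 95% band
covering the true curve at every observed point at an average width of
1.30. `gamma1` is the posterior of the Laplace scale tau: the data chose a
moderate amount of smoothing.

A full penalty comparison over replicated datasets is one call:

```r
cfg <- sim_config("double_hump", K = 7, penalty = "lasso",
                  n_replicates = 100, master_seed = 1)
run_study(cfg)   # tibble of MASE/MACP/MACL, full curve + boundary strips
```

For shell use, `inst/cli/bspmm.R` wraps the same functions as
`simulate`, `fit`, `study` and `summarize` subcommands driven by YAML
configs, writing draws, summaries, smooth-curve tables and a plain-text
report; `fit` exits nonzero when any Gelman-Rubin sqrt(R-hat) exceeds 1.03
(unless `--no-strict`).

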