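# bnpgrowth

Bayesian non-parametric growth curve modeling for longitudinal data
whose measurement errors may be anything but normal.

Applied longitudinal researchers routinely fit linear growth curve
models

```
y_i = Λ b_i + e_i,    b_i = β + u_i,    u_i ~ N₂(0, Ψ)
```

with subject-level random intercepts and slopes, and routinely get
burned by the normality assumption on the errors `e_i`: a handful of
contaminated measurements inflates the error variance and biases the
growth parameters. `bnpgrowth` replaces the error distribution with a
Dirichlet process mixture of zero-mean multivariate normals,

```
e_i | Φ_i ~ N_T(0, Φ_i),    Φ_i | G ~ G,    G ~ DP(α, G₀),
```

fitted by a truncated stick-breaking Gibbs sampler (compiled with
RcppArmadillo). The mixture grows as many error components as the data
demand — outliers land in their own components instead of corrupting
the clean majority — and the number of occupied components K is
governed by the precision parameter α, whose prior is the package's
central concern: the asymptotic law K = 1 + Poisson(α(γ + log N)), the
exact two-gamma conditional posterior of α with its augmented-variable
sampler, and a simulation-study harness for comparing non-informative,
weakly informative, accurate and inaccurate gamma priors on convergence
rates and parameter recovery.

## Worked example

Simulate a 200-subject, four-occasion panel from the linear growth
process (mean intercept 6.2, mean slope 0.3, error variance 0.5),
contaminate 10% of the observations at each occasion with mean-shifted
outliers (at least five error SDs above each subject's own trajectory),
and fit the model under the weakly informative Gamma(2, 2) prior:

```r
library(bnpgrowth)

panel <- simulate_panel(200, seed = 42)
panel <- contaminate(panel, outlier_spec(0.10), seed = 43)
fit <- bnp_gcm(panel, dpm_spec(alpha_prior = "weak"),
               n_iter = 10000, burn_in = 5000, seed = 44)
summary(fit)
#>  parameter    mean     sd hpd_lower hpd_upper geweke_z converged
#>     beta_L  6.3342 0.1031    6.1384    6.5353  -0.5467      TRUE
#>     beta_S  0.3216 0.0433    0.2413    0.4117   2.2364     FALSE
#>   sigma2_L  0.9230 0.1846    0.5965    1.3062   0.3527      TRUE
#>   sigma2_S  0.1115 0.0276    0.0601    0.1646   0.9350      TRUE
#>   sigma_LS -0.0130 0.0562   -0.1268    0.0918   0.0539      TRUE
#>   sigma2_e  5.1143 0.6321    3.9746    6.4287   0.9096      TRUE
#>      alpha  1.2550 0.6380    0.2173    2.4931  -1.5154      TRUE
#>          K  7.3120 2.7249    3.0000   13.0000  -1.5435      TRUE
```

Reading the output: the growth parameters stay close to their
generating values (`sigma2_L` ≈ 1, `sigma2_S` ≈ 0.1) despite the
contamination, while the derived marginal error variance `sigma2_e`
(the stick-weighted mixture scale, here ≈ 5.1) absorbs the outliers —
under contamination it estimates the mixture's marginal scale, not the
clean 0.5. The mixture occupied K ≈ 7 components to do so. `beta_L` is
pulled upward by about 0.13 because the contamination is one-sided;
that bias grows with the outlier proportion. Each row also carries its
Geweke stationarity statistic (first 10% vs last 50% of the chain,
converged iff |z| < 1.96) and the 95% highest-posterior-density
interval.

The analytic side needs no simulation at all:

```r
cluster_count_table(alpha = 1, n = c(200, 600), probs = c(.05, .5, .95))
#>     n alpha prob  k
#> 1 200     1 0.05  3
#> 2 200     1 0.50  7
#> 3 200     1 0.95 11
#> 4 600     1 0.05  4
#> 5 600     1 0.50  8
#> 6 600     1 0.95 13
```

Other entry points: `run_condition()`/`run_study()` for the replication
harness (bias, ASE, ESE, MSE, HPD coverage, Geweke-based convergence
rates across prior × sample-size × contamination grids),
`sample_alpha_augmented()` and `alpha_posterior_mixture()` for the
precision-parameter theory, `geweke_z()`/`hpd_interval()` as standalone
diagnostics, and a thin CLI (`inst/cli/bnpgcm`) with `simulate`, `fit`,
`diagnose`, `study` and `table1` subcommands.

See `vignettes/bnp-growth-modeling.Rmd` for the model, the two
precision-parameter update rules and when they differ, the
base-measure structure decision, and known limitations.

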