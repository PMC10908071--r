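# skewsplmm

Bayesian semiparametric mixed-effects models for skewed longitudinal data.

Clinical follow-up biomarkers — the motivating case is the estimated
glomerular filtration rate (eGFR, mL/min/1.73m²) measured repeatedly in
chronic kidney disease patients — typically decline non-linearly in time and
are asymmetrically distributed both between and within patients.  The
standard Gaussian linear mixed model is doubly misspecified for such data:
the linear time effect misses the trajectory shape, and the normality
assumptions on random effects and errors lack robustness to skewness.

`skewsplmm` fits the semiparametric partially linear mixed-effects model

    y_i = Z_i α + R_i φ_i + ε_i,
    φ_i ~ ST(0, Σ_φ, δ_φ),   ε_i ~ ST(0, σ²_ε I, δ_ε I),

where `Z_i = [1, covariates, Φ(t_i)]` and `R_i = [1, Φ(t_i)]` with `Φ(t)` a
natural cubic spline basis of time on percentile-based knots, so each
subject gets its own deviation from the population trajectory.  Random
effects and errors may each be multivariate normal, skew-normal or skew-t
(the four named flavors MoSTST, MoNST, MoSNSN, MoNN, plus a fully parametric
linear-time variant FPLMEM).  The skew-t laws are represented hierarchically
via positive truncated-normal latents and gamma scale mixing, which makes
every Gibbs block conjugate except the degrees of freedom (random-walk
Metropolis-Hastings on `log(ρ − 3)`).  The sampler core is C++
(RcppArmadillo); a full 3-chain fit of 400 subjects × 11 visits takes about
a minute on one core.

Also included: DIC model comparison (conditional on the latent nodes, with
the convention recorded), Geweke / Brooks-Gelman-Rubin / ACF convergence
diagnostics, a skewed-data simulation generator, and a replication harness
reporting Est / relative bias / RMSE / coverage per parameter and DIC per
model.  The methods vignette (`vignettes/skewsplmm-methods.Rmd`) documents
the model, the latent-centering parametrization, priors, and all numerical
choices.

## Worked example

Simulate a skewed longitudinal study (400 subjects, 11 visits; intercept
27.5, covariate effects −5 and −4, spline coefficients −9, −25, −5; shifted
Gamma(2,1) − 2 random effects and errors), fit the skew-t/skew-t model, and
compare flavors by DIC:

```r
library(skewsplmm)

sim <- simulate_dataset(sim_design(), seed = 1)
cfg <- config_from_label("MoSTST", fixed_covariates = c("Z1", "Z2"),
                         mcmc = mcmc_control(chains = 3, iter = 8000,
                                             burnin = 3000, thin = 5, seed = 1))
fit <- run_mcmc(sim$data, cfg)
subset(posterior_summary(fit), grepl("alpha", parameter))
```

```
           parameter       mean         sd      lower      upper
1 alpha[(Intercept)]  27.738743 0.07043334  27.604794  27.872574
2          alpha[Z1]  -5.224594 0.09284833  -5.392986  -5.038537
3          alpha[Z2]  -4.168620 0.08010748  -4.358489  -4.030617
4         alpha[ns1]  -8.987419 0.11141688  -9.252197  -8.787886
5         alpha[ns2] -24.996383 0.12661459 -25.223908 -24.723975
6         alpha[ns3]  -4.821482 0.06983451  -4.948798  -4.691110
```

The posterior means sit close to the generating values (27.5, −5, −4, −9,
−25, −5); `Z1`/`Z2` are the binary covariates and `ns1..ns3` the population
spline coefficients.  A Gaussian fit of the same data
(`config_from_label("MoNN", ...)`) prints a far larger error variance and a
much larger DIC — `dic(fit)` reports `DIC`, the deviance at the posterior
mean, and the effective number of parameters, and on this dataset the
Gaussian flavor is worst by several thousand.  Convergence is checked with
`diagnostics_report(fit)` (Geweke |z| < 1.96, BGR < 1.1 gates).

A thin command-line interface with `simulate`, `fit`, `diagnose`, `dic` and
`replicate` subcommands lives at `inst/cli/skewsplmm-cli.R`.

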