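---
title: "Semiparametric mixed-effects models with skew distributions: methods and design"
author: "skewsplmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semiparametric mixed-effects models with skew distributions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Longitudinal biomarkers such as the estimated glomerular filtration rate
(eGFR, mL/min/1.73m²) in chronic kidney disease follow-up are measured
repeatedly per patient, decline non-linearly in time, and are markedly
asymmetric both across patients and within patients.  `skewsplmm` fits a
semiparametric partially linear mixed-effects model (SPPLMEM) for a response
$y_{ij}$ of subject $i$ at time $t_{ij}$:

$$
y_i = Z_i \alpha + R_i \varphi_i + \varepsilon_i,
\qquad
Z_i = [\,1,\; x_i,\; \Phi(t_i)\,],
\quad
R_i = [\,1,\; \Phi(t_i)\,],
$$

where $\Phi(t)$ collects natural cubic spline bases of time (the
nonparametric population time effect), $\alpha$ stacks the parametric
covariate effects and the population spline coefficients, and $\varphi_i$
holds a random intercept plus subject-specific spline-coefficient
deviations, so each subject bends the population trajectory its own way.
With the default 2 interior knots this gives a 4-dimensional random effect.
A fully parametric variant (`linear_time = TRUE`, "FPLMEM") replaces the
spline block with a linear time term and random intercept + slope.

Random effects and errors may each be multivariate normal (N), skew-normal
(SN) or skew-t (ST):

$$
\varphi_i \sim ST_{q+l,\rho_\varphi}(0, \Sigma_\varphi, \delta_\varphi),
\qquad
\varepsilon_i \sim ST_{m_i,\rho_\varepsilon}
  (0, \sigma^2_\varepsilon I, \delta_\varepsilon I).
$$

The four flavor pairs studied throughout are MoSTST (ST/ST), MoNST (N/ST),
MoSNSN (SN/SN) and MoNN (N/N, the conventional Gaussian mixed model).

## Hierarchical representation and the sampler

The skew families are represented through positive truncated-normal latents
$W$ and gamma scale-mixing variables $v$:

$$
\begin{aligned}
y_i \mid \varphi_i, W_{\varepsilon i}, v_{\varepsilon i}
  &\sim N\!\big(Z_i\alpha + R_i\varphi_i
      + \delta_\varepsilon (W_{\varepsilon i} - c_\varepsilon),\;
      v_{\varepsilon i}^{-1}\sigma^2_\varepsilon I\big),\\
\varphi_i \mid W_{\varphi i}, v_{\varphi i}
  &\sim N\!\big(\delta_\varphi \circ (W_{\varphi i} - c_\varphi),\;
      v_{\varphi i}^{-1}\Sigma_\varphi\big),\\
W_{\cdot i} \mid v_{\cdot i} &\sim
  N(0, v_{\cdot i}^{-1} I)\, I(W > 0),
\qquad
v_{\cdot i} \mid \rho_\cdot \sim \Gamma(\rho_\cdot/2,\, \rho_\cdot/2),
\end{aligned}
$$

with one mixing scalar per subject, shared across that subject's
coordinates/visits.  Every block then has a conjugate full conditional
(multivariate normal for $\alpha$, $\varphi_i$, $\delta_\varphi$; univariate
truncated normal for each $W$ coordinate; inverse-gamma for
$\sigma^2_\varepsilon$; inverse-Wishart for $\Sigma_\varphi$; gamma for the
$v$'s), except the degrees of freedom $\rho > 3$, which use random-walk
Metropolis-Hastings on $\log(\rho - 3)$.  The update cycle is fixed as
fixed effects → random effects → truncated latents → scales → skewness →
mixing → dof: the cheap conjugate draws come first and any fixed valid order
leaves the stationary distribution unchanged.  The full conditionals are
derived by us and each block is certified in the test suite against a
closed-form oracle on a toy where the conditional is hand-derivable.

### Centering the latent skew term

The constants $c_\varepsilon, c_\varphi$ implement the package's default
*centered* parametrization: $c$ is the prior mean of a $W$ coordinate,
$c(\rho) = \sqrt{2/\pi}\, E[v^{-1/2}]$ (and $\sqrt{2/\pi}$ for SN).  With
$c = 0$ (option `center = FALSE`) the representation is the raw location-0
form, under which the *mean* of a skew error is
$\delta_\varepsilon E[v^{-1/2}]\sqrt{2/\pi} \neq 0$, so the intercept
estimate is shifted by exactly that amount and the population spline
coefficients are shifted by $\delta_{\varphi k} E[W]$.  Centering removes
these offsets so that $\alpha$ retains its interpretation as the marginal
mean structure and estimates are directly comparable with the generating
values of simulation studies; this is the design choice behind the package's
unbiased intercept recovery.  Because $c$ depends only on $\rho$ (not on the
per-subject $v$), all conjugacies survive; the dof MH target simply gains
the Gaussian data terms that depend on $\rho$ through $c(\rho)$.

Flavor degeneracies are handled by pinning: $\delta \equiv 0$ and $W$ unused
for N, $v \equiv 1$ for SN and N.  Pinned parameters are dropped from the
recorded draws.

### Spline details

Interior knots sit at equally spaced percentiles of the observed measurement
times (linear-interpolation percentiles, `quantile` type 7; the convention
is stated openly because percentile definitions differ).  The basis is the
natural cubic spline — piecewise cubic, $C^2$, linear beyond the boundary
knots — with the intercept excluded from the spline block (it lives in the
parametric part), giving `n_interior + 1` columns.  Individual basis columns
are not unique across constructions; what is identified is the spanned
space, and the tests verify span equivalence with an independently coded
truncated-power construction to 1e-8.  Evaluation outside the boundary knots
extrapolates linearly, so follow-up times in new data may exceed the fitting
range.  Note that on a balanced repeated grid the percentiles of the stacked
time column land on grid values (e.g. knots {3, 7} for 400 copies of
0..10), which is the same rule a scientist would apply to irregular
real-world visit times.

### Priors, initialization, tuning

Defaults are weakly informative: N(0, 100) for every fixed-effect and
skewness component, IW(0.01 I, d) for $\Sigma_\varphi$, IG(0.01, 0.01) for
$\sigma^2_\varepsilon$, and Exp(0.5) truncated to $(3,\infty)$ for both dof
(the truncation keeps the first three skew-t moments finite).
Initialization is moment-based and deterministic up to a small seeded jitter
on the skewness: least squares for $\alpha$ (with a rank check that names
collinear columns), residual variance for $\sigma^2_\varepsilon$, identity
$\Sigma_\varphi$, $\varphi_i = 0$, $W = v = 1$, $\rho = 5$.  The MH step on
$\log(\rho-3)$ starts at 0.3 and is Robbins-Monro-adapted toward acceptance
0.35 during burn-in only, so the post-burn-in kernel is a fixed Markov
kernel.  The MCMC defaults (3 chains × 8000 iterations, burn-in 3000, thin
5) are the problem sizes used throughout the package's own evaluation;
heavier settings are a one-line change in `mcmc_control()`.

## Model comparison and diagnostics

`dic()` reports the deviance information criterion
$\mathrm{DIC} = \mathrm{Dev}(\bar\Omega) + 2 p_D$ with
$p_D = \overline{\mathrm{Dev}} - \mathrm{Dev}(\bar\Omega)$.  The deviance is
*conditional* on the random effects and all latent nodes — the convention a
graphical-model sampler uses when these are stochastic nodes — which makes
values comparable across the four flavors; the conditioning convention is
recorded in the result, and a marginal-errors variant (integrating the
truncated latents to the skew density, conditional on mixing) is available
for sensitivity.  Posterior means of $\Sigma_\varphi$ are taken elementwise.
Absolute DIC values depend on the conditioning convention and the dataset
realization; the robust, reproducible statement is the *ordering* — on
skewed data the Gaussian flavor is worst — and that is what the package's
acceptance surface gates.

Convergence checking follows the standard protocol: Geweke z (early 10% vs
late 50% segment means, spectral variance at frequency zero via a Bartlett
lag window of 4% of the segment — the test names the statistic, not the
estimator, so the estimator choice is stated here), the Brooks-Gelman-Rubin
potential scale reduction reported as the scalar statistic, and
autocorrelations.  Pass gates are $|z| < 1.96$ and BGR $< 1.1$.

## The simulation harness

`sim_design()` fixes the study conditions: 400 subjects, 11 equally spaced
times 0..10 (4,400 observations), $\alpha = (27.5, -5, -4)$,
$\lambda = (-9, -25, -5)$, subject-constant Bernoulli covariates with
probabilities 0.24 and 0.44, and every random-effect component and error
drawn i.i.d. from Gamma(shape 2, scale 1) shifted by $-2$ — mean 0, variance
2, skewness $\sqrt 2$.  The gamma parametrization is read as shape-scale,
consistent with the $-2$ centering.  `run_replications()` simulates,
fits each requested flavor with independently seeded chains, and aggregates
Est, relative bias, RMSE and 95% coverage per parameter plus DIC per flavor,
with per-replication CSV checkpoints for resumability.  The replication
count is configurable (there is no canonical value); comparisons against
published cell values must budget for both replication and MCMC noise.

What the generator emulates — irregularly skewed, non-linearly trending
trajectories with subject-level heterogeneity — and what it does not:
visit-time irregularity and dropout, time-varying covariates, measurement
rounding, and any dependence between covariates and random effects.  Passing
tests therefore certify the estimator under the stated conditions, not
robustness to those real-data features.

Two deliberate interpretive points, decided once:

* The shifted-gamma generating law has variance 2 per component, which does
  not map onto the skew-t scale parameters printed in published
  variance-component rows (e.g. $\sigma^2_\varepsilon = 0.5$); no stated
  mapping exists, so variance-component recovery is reported but not gated.
* Under this mean-zero generator a correctly specified Gaussian mixed model
  estimates the intercept consistently; the package's evaluation therefore
  gates Gaussian misspecification through the DIC ordering and the error
  variance, not through an intercept shift.

## Numerical choices

* Positive truncated-normal draws use plain rejection near the bulk and
  exponential rejection sampling in the far tail, stable for means far below
  zero.
* Multivariate normal conditionals are drawn via Cholesky factors of the
  precision; the inverse-Wishart via the Bartlett decomposition, with up to
  10 retries (then a hard error) if a sampled covariance fails positive
  definiteness.
* A constant chain makes the Geweke statistic 0 with a degenerate flag;
  equal-tailed (2.5%, 97.5%) credible intervals are the default with HPD
  behind a flag.
* All randomness flows through R's RNG, in C++ included, so a single master
  seed makes every fit, replication study and archive bit-reproducible.

## Known limitations

Skewing matrices are diagonal (elementwise $\delta$), matching the model's
indexing; general skew-elliptical families are out of scope, as are
penalized knot selection, dropout/censoring mechanisms, WAIC/LOO, and
Hamiltonian samplers.  The random-effect skewness components
$\delta_\varphi$ are weakly identified at moderate subject counts and mix
slowly; their chains should be read with the diagnostics report in hand.
The dof MH tuning is this package's own scheme, stated above, not a
reproduction of any external default.
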