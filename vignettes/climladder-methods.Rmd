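---
title: "Methods: a ladder of models for climate-driven conflict counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a ladder of models for climate-driven conflict counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models the package fits, the assumptions they
make, the choices made where the design was genuinely open, and what the
synthetic-data tests do and do not demonstrate about real data.

## The data and the regressors

The universal input is a balanced region-by-month panel: one non-negative
integer conflict-event count per region and month, together with three
climate regressors. The temperature anomaly TA (°C) is the deviation of a
monthly series from its calendar-month climatology over a baseline window,
smoothed with a trailing 3-month mean (`monthly_anomaly()`,
`rolling_mean()`). Drought length DL (months) is the running count of
consecutive months with strictly positive TA (`drought_length()`), so DL
is a deterministic transform of TA — the two are substantially correlated
by construction, which matters for interpreting their separate
coefficients. PA is the precipitation anomaly on the same construction.

The rolling window is *trailing* rather than centred: the regressor at
month t must be a function of information available at t for the causal
ordering to make sense. The first `window - 1` months average over the
months available so far, preserving panel balance (configurable to `NA`
them out instead).

`climate_forcing()` aggregates one climate column into a single
country-wide period series. The median-ratio form
`C_t = Σ_i c_it / Q_i(.5)` emphasises common threshold exceedance but is
undefined when a region's median is near zero — exactly the situation for
anomaly series. The guard is a hard error (floor `1e-6` on the absolute
median) pointing to the standardized-deviation form
`C_t = Σ_i (c_it − mean_i)/sd_i`, which is the default for synthetic
anomaly panels. Both modes are first-class; nothing in the package guesses
a denominator.

## The Gaussian fixed-effects rung

`fit_fe_ols()` estimates the linear model with region, year-month and
region-by-calendar-month intercepts. The fixed effects are absorbed by
alternating within-group demeaning iterated to a `1e-10` change; the dummy
expansion path (`method = "dummy"`) is retained as a cross-check and the
two agree to `1e-8` relative on every panel the suite generates. The
*within R²* follows the convention of reporting the share of the
region-demeaned outcome variation the model explains; its adjusted version
corrects for the absorbed degrees of freedom (number of linearly
independent FE coefficients plus slopes). The Gaussian AIC counts all
absorbed coefficients plus the residual scale; since AIC conventions for
absorbed-FE models differ across implementations, the parameter count is
part of the fit object so alternative conventions can be reconciled.

`hac_vcov()` is the spatial-temporal sandwich estimator: scores of
observation pairs enter the meat weighted by a spatial kernel over the
great-circle distance between their region centroids (haversine, mean
Earth radius 6371.0088 km) and a serial kernel over their month lag. The
defaults — uniform kernels, 263 km distance cutoff, 4 month lag cutoff —
correspond to the neighbouring-centroid distance and dependence horizon of
the Somalia panel the design targets. Within-region pairs sit at distance
zero and are always inside the spatial cutoff; with both cutoffs at zero
the estimator collapses to White's HC0, a property the suite asserts. The
serial weighting is the corrected one (weight one for every lag within the
cutoff under the uniform kernel). The meat is symmetrized; if it is not
positive semidefinite, negative eigenvalues are clipped at zero with a
warning and a flag — the raw estimator is available via `psd_fix = FALSE`.
No small-sample degrees-of-freedom correction is applied.

Count data violate the Gaussian error assumption in a specific, visible
way, and `gaussian_diagnostics()` makes it visible: standardized
residuals, normal Q-Q coordinates, Kolmogorov–Smirnov and Shapiro–Wilk
tests, and outlier flags at |z| > 3. The KS test on integer-valued
residual distributions involves ties; the tie warning is suppressed, the
statistic is reported as is.

## The negative binomial rung

`fit_nb_glm()` is the NB2 GLM with log link: variance `mu + mu²/Θ`, fixed
effects as explicit dummy columns (there is no absorption shortcut for a
non-identity link; at panel scale the dense design is unproblematic). The
fitting engine is the standard alternating IRLS with profile maximum
likelihood for Θ (`MASS::glm.nb`); the package computes its own
log-likelihood (checked in the suite against a term-wise gamma-function
sum at `1e-8`) and reports `AIC = -2 loglik + 2 (coefficients + 1)`, the
+1 being Θ. If the alternation destabilises — equidispersed data push Θ
toward infinity — the fit restarts from Θ = 1, which recovers the Poisson
limit gracefully. FE groups whose counts are all zero have coefficients
unbounded below (separation); they are detected up front, warned about and
flagged on the fit rather than silently regularized.

`nb_quantile_residuals()` implements randomized quantile residuals: u
drawn uniformly between the fitted NB CDF at y−1 and at y, mapped through
the standard normal quantile. Under the true model they are exactly
standard normal, which makes them the count analogue of the Gaussian
residual diagnostics. Observations whose CDF interval lies beyond
`1 − 1e-12` are capped at `qnorm(1 − 1e-12)` ≈ 7.03 and flagged.

## The Bayesian ladder

`hier_model_spec()` + `build_model()` + `fit_bayes()` cover three rungs:

- `pooling = "none"`: shared slopes, unpooled region and period
  intercepts with weakly regularizing normal(0, 5) priors — the Bayesian
  counterpart of the single-level GLM. Posterior medians of the slopes
  agree with the frequentist MLE within Monte Carlo error (asserted in
  the suite).
- `pooling = "region"`: region coefficient vectors `(a_i, b_i, c_i, f_i)`
  drawn from a 4-variate normal with estimated hypermeans and covariance,
  plus the group-mean covariates `T̄A_i, D̄L_i, P̄A_i` whose coefficients
  `η₁..η₃` absorb correlation between the region effects and the
  regressors (the within-between correction). Period intercepts stay
  unpooled. The region-month interaction is omitted from the multilevel
  rungs.
- `pooling = "region_time"`: additionally replaces the free period
  intercepts with `w_t ~ normal(ψ₀ + ψ₁ T̄A_t + ψ₂ D̄L_t + ψ₃ C_t, σ_w)`.
  Only this rung has a generative model for *new* periods, which is why
  out-of-sample projection requires it.

A Gaussian-family variant (`family = "normal"`, identity link) of any
rung supports the comparison with the original functional form.

**Backend and parameterization.** The sampler is JAGS (adaptive
Gibbs/slice sampling) through rjags — the MCMC engine available to this
package. Two consequences are worth stating plainly. First, a divergence
count is a Hamiltonian-sampler concept and is recorded as `NA`;
convergence is judged on rank-normalized split R-hat (< 1.01) and bulk
ESS (> 400), computed per parameter, with failures *flagged on the fit*
rather than silently accepted. Short exploratory chains will be flagged;
that is intended behaviour, not an error. Second, the covariance prior is
the scaled-Wishart construction: zero-mean raw coefficient vectors with a
Wishart(I, 5) prior on their precision (degrees of freedom = dimension + 1,
giving near-uniform marginal correlations), scaled elementwise by
half-normal factors and shifted by the hypermeans. This is the
non-centred form that keeps the Wishart conjugate under Gibbs; an LKJ
prior on the correlation matrix would be the natural choice under a
Hamiltonian backend but has no JAGS sampler. All prior scales
(`default_priors()`) are weakly informative package defaults — normal(0, 5)
on location parameters, half-normal(0, 1) scale factors, half-normal(0, 1)
on `1/√Θ`, half-normal(0, 2) on σ_w — and every one is overridable in the
spec; they are this package's choices, deliberately mild at the data
scales involved.

Seeding: one master seed; chain seeds are derived by fixed offsets, so a
fit is bit-reproducible given the same backend version. The pointwise
log-likelihood matrix (draws × observations) is reconstructed in R from
the monitored parameters and checked draw-by-draw against the NB density
in the suite. Group-mean covariates are computed once from the observed
panel, not per draw.

`summarize_posterior()` reports the median, the MAD-scaled SD
(`1.4826 × median(|x − median|)`, consistent for a normal), and the
central 95% interval — robust summaries suited to skewed posteriors.

## Evaluation

`psis_loo()` implements Pareto-smoothed importance sampling
leave-one-out: per observation, log importance ratios are the negative
log-likelihoods; the largest 20% (minimum tail 5) are replaced by expected
order statistics of a generalized Pareto distribution fitted to the tail
exceedances by the Zhang–Stephens profile posterior-mean method with the
usual weak prior on the shape; weights are truncated at the raw maximum.
Observations with tail shape k̂ > 0.7 are counted and reported, not refit.
The suite checks PSIS-LOO against an exact leave-one-out oracle — grid
quadrature over a two-parameter NB regression posterior, reweighted
without each observation in turn — at n = 40, within two SEs of the
pointwise difference. `elpd_compare()` reports differences against the
best model with `se = sqrt(N · var(pointwise differences))`.

`ppc_replicate()` simulates full panels from the likelihood at posterior
draws (resampling draws with replacement if more replicates than draws
are requested) and compares a test statistic against its observed value
with a two-sided posterior predictive p-value. The headline statistic is
the proportion of zeros; since Gaussian replicates are continuous and
would almost surely contain no exact zeros, the statistic rounds values
to the nearest integer first — this preserves the Gaussian/NB contrast
while keeping the statistic well-defined across families.

## The synthetic generator

`simulate_panel()` produces panels with the statistical structure the
analysis assumes: 18 regions × 156 months starting 1997 by default, to
match the target panel's dimensions. Region centroids sit on a jittered
grid over a Somalia-sized box; temperature and precipitation anomaly
series are a seasonal sine (amplitude 0.3) plus AR(1) noise (coefficient
0.6, innovation SD 0.5) whose innovations are spatially correlated with
exponential decay (range 300 km, so the 263 km HAC cutoff is exercised);
DL is always derived from TA, never simulated separately. Region
coefficients come from the configured MVN (hypermeans 0.10, 0.05, −0.05,
−0.5; between-region SDs 0.10, 0.05, 0.08, 0.70; common correlation 0.2);
the confounding device adds `confounding_strength × standardized(T̄A_i)`
(default 0.8) to the baseline `f_i`, inducing exactly the region-level
treatment–effect correlation the group-mean correction exists to absorb.
Period effects follow the forcing-driven level model (ψ = (0, 0.5, −0.05,
0.02), σ_w = 0.3) and counts are NB2 with Θ = 0.8. These values were
chosen once to produce Somalia-like marginals — a 50–70% zero share with
occasional counts in the tens — and are not calibrated to any published
estimate.

What the generator does *not* emulate: the real panel's kriged gridded
climate inputs, reporting artefacts in event counts, non-stationarity of
the conflict process, or any attempt to match the joint ACLED/CRU
distribution. Passing tests demonstrate that the estimators recover the
structure they assume, not that the assumptions hold for Somalia.

`scenario_shift()` builds "+k SD" climate scenarios with per-region
historical SDs; shifting TA re-derives DL so the deterministic TA→DL link
always holds. `project()` propagates parameter uncertainty, period-level
uncertainty (out-of-sample w_t are sampled from their level model, with
the period means and forcing recomputed from the scenario panel so the
level model's inputs are scenario-consistent), and NB sampling noise.

## Test problem sizes

The suite favours small, deep checks: exact oracles (literal double sums,
dummy expansion, term-wise likelihoods, grid quadrature) on toy panels,
and MCMC-based checks at 6 regions × 48 months with 2 chains × 400
retained draws — sizes at which the Gibbs sampler mixes well enough for
median-level comparisons while keeping the default run fast. The
parameter-recovery study in the acceptance suite runs 8 replicates per arm
at 18 regions × 24 months; `run_recovery_study()` defaults to the full 18
× 156 design for users who want the long version. The acceptance script
fits the full ladder at 18 × 156 with 2 chains × 400 draws.

## Known limitations and observed behaviour

- **Priors.** The weakly informative set is provisional by design; there
  is no claim that it matches any particular published specification.
- **Gibbs mixing.** The group-mean coefficients η and the between-region
  scales mix slowly; hypermean inferences are robust in the recovery
  study, but η posteriors at small region counts are wide and their ESS
  flags fire under short chains.
- **The within-between contrast is regime-dependent.** In simulation, the
  *fully pooled* naive model (one common intercept) shows severe slope
  bias under the generator's confounding, and the group-mean-corrected
  model removes it — the suite asserts this. For the *partially pooled*
  model, however, omitting the η-terms produces only a mild hypermean
  bias once each region contributes a few dozen observations: the free
  region intercepts absorb most of the region-level confounding
  themselves. The correction then matters mainly for interpreting the
  between-region structure, not for rescuing the within slopes. The
  acceptance suite states the strong (3×) form of the contrast for the
  partially pooled pair and records its empirical failure rather than
  weakening the check.
- **ELPD gaps between adjacent NB rungs can be small.** With modest true
  slope heterogeneity the region-pooled rung improves on the single-level
  NB model by an amount comparable to its paired SE on a single synthetic
  panel; the suite therefore asserts strict ordering only where the
  generator guarantees it and uses paired SEs elsewhere.
- **No spatially structured random effects** (regions are exchangeable in
  the multilevel rungs; spatial dependence enters only through the HAC
  covariance of the frequentist rung and the generator), no zero-inflated
  or hurdle variants, no K-fold or leave-one-region-out CV.
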