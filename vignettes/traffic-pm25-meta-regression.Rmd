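---
title: "Joint meta-regression of urban traffic-related PM2.5 and its health impact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint meta-regression of urban traffic-related PM2.5 and its health impact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trafficpm)
```

## The scientific problem

Source-apportionment studies decompose a city's measured PM2.5
concentration into contributions from source categories, traffic among
them. The WHO maintains a database of such studies; each urban record
reports an overall PM2.5 concentration (µg/m³) and the percentage
contributed by traffic (tailpipe plus non-tailpipe). Pooling these
records across cities makes three questions answerable:

1. How strongly are overall and traffic-related concentrations coupled
   across cities, after adjusting for study-level covariates?
2. If a city removed *all* traffic emissions, what is the probability
   that its remaining (non-traffic) PM2.5 would still exceed the WHO
   annual guideline of 5 µg/m³?
3. How much premature mortality would that removal avert, given the
   non-linear dose-response of PM2.5?

`trafficpm` implements this pipeline end to end, together with a
synthetic-data generator so that every stage is testable without access
to the restricted database.

## The joint model

For record $i$, let $y_{1i} = \log(\text{traffic PM}_{2.5})$ and
$y_{2i} = \log(\text{overall PM}_{2.5})$, where the traffic
concentration is the overall concentration times the reported traffic
share. We assume

$$
(y_{1i}, y_{2i})^\top \sim \mathrm{MVN}(\mu_i, \Sigma), \qquad
\mu_{ki} = \eta_k + \gamma_k^\top X_{ki},
$$

a bivariate ("seemingly unrelated") regression: the two equations may
use different regressors, and the residual covariance $\Sigma$ carries
the cross-outcome dependence. The posterior of
$\rho = \Sigma_{12}/\sqrt{\Sigma_{11}\Sigma_{22}}$ quantifies the
correlation between traffic-related and overall concentrations.

Default regressors (chosen to reflect the covariates available in the
WHO database):

* traffic equation: log city population (millions), latitude/10
  (signed), sea-salt-reported indicator, published-after-2005 indicator,
  and location dummies for North America/Oceania/Japan and
  Northwestern/Western Europe;
* overall equation: the same but with the rest-of-Europe dummy in place
  of the publication-period indicator (exploratory analyses of these
  data find a period effect only for the traffic share).

Reference categories are: sea salt not reported, published on or before
2005, rest of the world. "After 2005" is strict: a 2005 study is in the
reference group.

### Priors and computation

Every intercept and coefficient has a normal(0, 100) prior
(variance 100). The residual precision has a Wishart prior in the
WinBUGS convention, $\Sigma^{-1} \sim \mathrm{Wishart}(R, K)$ with
$K = 2$ and $R = \mathrm{diag}(0.01)$, i.e. prior expectation
$K R^{-1}$; this convention is stated explicitly because the scale
versus rate ambiguity of the Wishart is a classic source of silent
errors. Both full conditionals are conjugate:

* all intercepts and coefficients jointly, given $\Sigma$, are
  multivariate normal (the generalized-least-squares form of the
  stacked two-equation system), and
* $\Sigma^{-1}$, given the residuals, is Wishart with scale $R + S$
  ($S$ the 2×2 residual cross-product) and $K + N$ degrees of freedom.

The sampler is therefore a plain two-block Gibbs scheme with no tuning
parameters. The defaults mirror the reference protocol for these data:
two chains of 15,000 iterations, the first 5,000 discarded, all 20,000
retained draws used without thinning. Convergence is monitored with the
Gelman-Rubin potential scale reduction factor per scalar parameter
(flag at 1.1). Because the coefficient block is drawn jointly and
exactly, convergence is fast; the diagnostic mainly guards against
design pathologies.

Numerical choices: chains are initialised at the per-equation
least-squares residual covariance scaled by a chain-specific factor
drawn in [1/2.5, 2.5] (the first coefficient draw is already from the
exact conditional, so only the $\Sigma$ start needs dispersion); every
$\Sigma$ draw is symmetrised as $(\Sigma + \Sigma^\top)/2$ and, on a
Cholesky failure, repaired with a 1e-10 ridge and counted in the fit
log; rank deficiency of either design matrix is an error that names the
collinear columns.

## Data curation rules

* Only urban site typologies are retained, and only records reporting a
  traffic share; removals are counted per rule in a retention log.
* `traffic_pm25 = overall_pm25 × traffic_share_pct / 100`; a share of
  exactly 0 is rejected with a reason (its log is undefined), and
  shares above 100 fail validation.
* Population enters as log of millions (`ln(pop/1e6)`), latitude as
  signed degrees divided by 10.
* Cities are assigned to 12 regions, collapsed to four location
  categories: North America/Oceania/Japan (Japan belongs here as a
  high-income country with comparable concentrations),
  Northwestern/Western Europe, rest of Europe, rest of the world.
* Records missing population or latitude are excluded (complete-case)
  and itemised; no imputation is attempted.
* Repeat measurements of one city stay as separate rows (the model has
  no within-city random effect); for prediction a city is represented
  by its most recent record's covariates by default, or by
  record-averaged covariates on request.

## The synthetic-data generator

The generator reads the model forward with known parameters, so
parameter-recovery and calibration tests can score against an exact
truth ledger. Defaults:

* Covariates are drawn independently: normal log population
  (mean −0.13, sd 1.68, in log-millions), normal signed latitude
  (mean 30.97, sd 23.61, clamped to ±90), Bernoulli(0.5) sea-salt
  reporting, Bernoulli(0.742) post-2005 publication, and a categorical
  region law matching the observed regional frequencies of the urban
  WHO sample (which induce location-category frequencies of roughly
  0.36, 0.11 and 0.23 for the three non-reference categories). Real
  covariates are correlated (latitude with region, notably); the
  generator does not model this, so tests passing on synthetic data say
  nothing about confounding patterns specific to the real database.
* True intercepts and coefficients default to values representative of
  a global urban sample (e.g. traffic intercept 2.54, overall intercept
  3.63 on the log µg/m³ scale). The residual covariance is not
  reported anywhere for these data, so it is a package choice: log-scale
  standard deviations 0.5 (traffic) and 0.4 (overall) with correlation
  0.6, picked once to make recovery tests well conditioned at n ≈ 200.
* Rows whose simulated traffic exceeds the overall concentration are
  rejection-resampled (outcomes only) so the share stays in (0, 100].
  Resampling, not truncation-by-clamping, keeps the outcome pair
  conditionally Gaussian below the cap; it does shift the *marginal*
  means slightly (the cap truncates $y_1 - y_2$ at 0), which the test
  suite checks against the exact truncated-normal expectation rather
  than pretending the cap is free.
* One master seed is split into substreams (covariates, outcomes), so a
  stage can be varied without disturbing the others. Regenerating a
  named fixture is byte-identical.

The packaged IER parameter tables are synthetic placeholders, **not**
Global Burden of Disease draws: lognormal spreads around invented
central values whose curve shapes reproduce the qualitative published
behaviour (shallow saturation for IHD/stroke, steeper sustained rise
for COPD/lung cancer/LRI, and a diabetes curve essentially flat above
~20 µg/m³). Real draw tables are accepted as CSV wherever IER draws are
consumed.

## City inference

Pushing a city's covariate vector through every retained draw gives
per-draw expected log concentrations $(\mu_1, \mu_2)$, hence
natural-scale traffic and overall concentrations, and non-traffic as
their difference. Two back-transforms are provided because "expected
concentration" is ambiguous for a lognormal: the default `median` uses
$\exp(\mu)$; `lognormal_mean` uses $\exp(\mu + \Sigma_{kk}/2)$. The
choice is recorded in the run manifest. In a given draw the predicted
traffic concentration can exceed the overall one (the equations are
separate); such draws keep their negative non-traffic value — they
simply count as below any positive threshold — and are tallied in a
warning counter, because clamping them to zero would bias exceedance
probabilities upward invisibly.

The exceedance probability of city $c$ is the fraction of draws in
which non-traffic PM2.5 is **at or above** the threshold (default
5 µg/m³, the 2021 WHO annual guideline); ties count as exceeding.

## Health impact

Relative risk follows the integrated exposure-response form
$RR(z) = 1 + \vartheta(1 - e^{-\omega z^\delta})$ with
$z = \max(0, \mathrm{PM}_{2.5} - x)$, the counterfactual threshold $x$
drawn uniformly on [2.4, 5.9] µg/m³ per parameter draw (independently
of $\vartheta, \omega, \delta$ unless the supplied draw file provides
joint draws). The traffic-removal scenario compares
$\mathrm{PM}_{b}$ = posterior-mean overall concentration with
$\mathrm{PM}_{cf} = \mathrm{PM}_b -$ posterior-mean traffic
concentration (floored at zero with a warning), and

$$\mathrm{PAF} = 1 - RR(\mathrm{PM}_{cf}) / RR(\mathrm{PM}_b),$$

averaged over 1000 parameter draws and reported as a percentage
(rounded to two decimals in tables; tests of strict inequalities use
the unrounded values). Pairing by posterior *means* — rather than
crossing MCMC draws with IER draws — matches the reference protocol for
these data; a full-uncertainty mode would be a natural extension but is
deliberately not the default, to keep reported numbers comparable.

Because the IER saturates, the PAF of a fixed relative traffic share
*falls* with increasing baseline concentration once both concentrations
sit on the flat part of the curve — the "negative returns" mechanism
most visible for diabetes. IHD/stroke draws carry an age-group label
(default "55-60"); no age group is hard-coded anywhere.

## Problem sizes used by the test suite

The suite exercises the sampler at the scale of the real analysis
(182 observations, 117 cities, two chains of 15,000 iterations) for
recovery and convergence checks, and uses 100 replicate datasets of 100
observations with 2,000 retained single-chain draws each for interval
calibration — enough replicates to estimate per-parameter 95% coverage
with a binomial standard error near 0.02. Closed-form oracles (the
conjugate normal posterior with known $\Sigma$, the GLS limit under
near-flat priors, truncated-normal moments for the share cap) are
computed independently of the sampler code paths they check.

## Known limitations

* The generator's covariate independence and lognormal outcome law are
  idealisations; passing recovery tests demonstrates correctness of the
  implementation, not adequacy of the model for the real database.
* No within-city random effect: repeated measurements of a city are
  treated as exchangeable given covariates.
* The packaged IER tables are synthetic; substantive health-impact
  numbers require real draw files.
* Percentage mortality reductions are relative to baseline burden;
  translating them into deaths requires external baseline mortality
  rates, which are out of scope.
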