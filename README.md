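# trafficpm

Joint Bayesian meta-regression of urban PM2.5 source-apportionment
studies, with guideline-exceedance and health-impact analysis for a
complete-traffic-removal counterfactual.

## What it does, and for whom

Source-apportionment studies report, for a city, the overall PM2.5
concentration and the percentage contributed by traffic. For
epidemiologists and air-quality policy analysts pooling such studies
(e.g. the urban records of the WHO source-apportionment database), this
package answers three questions:

1. **How coupled are traffic-related and overall PM2.5 across
   cities?** Writing `y1 = log(traffic PM2.5)` and
   `y2 = log(overall PM2.5)`, the package fits the bivariate
   meta-regression

   ```
   (y1i, y2i)' ~ MVN(mu_i, Sigma),   mu_ki = eta_k + gamma_k' X_ki
   ```

   with equation-specific regressors (log city population, latitude/10,
   sea-salt reporting, publication period, location category). Priors
   are normal(0, 100) on every coefficient and, on the precision,
   Wishart(R, K) in the WinBUGS convention with K = 2 and
   R = diag(0.01). The sampler is a custom two-block conjugate Gibbs
   scheme (joint GLS-form normal draw of all coefficients, Wishart draw
   of the precision); defaults are two chains of 15,000 iterations with
   5,000 burn-in. The posterior of
   `rho = Sigma12 / sqrt(Sigma11 Sigma22)` is the cross-outcome
   correlation of interest.

2. **Could a city meet the WHO annual guideline (5 µg/m³) without its
   traffic emissions?** Per posterior draw, city-level expected
   traffic/overall concentrations are formed from the city's
   covariates; the exceedance probability is the fraction of draws in
   which non-traffic PM2.5 (overall minus traffic) is at or above the
   threshold.

3. **How much mortality would traffic removal avert?** Using
   integrated exposure-response (IER) functions
   `RR(z) = 1 + theta (1 - exp(-omega z^delta))`,
   `z = max(0, PM2.5 - x)` with counterfactual threshold
   `x ~ U(2.4, 5.9)`, the population attributable fraction
   `PAF = 1 - RR(pm_cf)/RR(pm_b)` is averaged over 1000 parameter draws
   per endpoint (IHD, stroke, COPD, lung cancer, LRI, diabetes).

A synthetic-data generator reproduces the joint model forward from
known parameters (with covariate laws matching the urban WHO sample's
summary characteristics), so the full pipeline is testable without the
restricted database. Packaged IER tables are synthetic placeholders,
not GBD draws; real draw files are accepted as CSV.

## Worked example

```r
library(trafficpm)

dir <- tempfile()
fx  <- make_fixture("small", dir)            # 50-record synthetic dataset
recs <- read_records(fx[["records"]])
cur  <- curate_records(filter_records(recs))
fit  <- fit_joint_model(build_design(cur), pm_priors(),
                        mcmc_config(n_chains = 2, n_iter = 4000,
                                    n_burn = 1000, seed = 1))
posterior_summary(fit)[1:4, ]
#>                   parameter  mean    sd   lower  upper
#> 1       traffic:(Intercept)  2.47 0.205  2.0630  2.869
#> 2     traffic:ln_population  0.20 0.046  0.1086  0.289
#> 3             traffic:lat10  0.06 0.033 -0.0068  0.125
#> 4 traffic:sea_salt_reported -0.40 0.159 -0.7090 -0.086
```

Coefficients are on the log µg/m³ scale: here a unit increase in log
population (millions) multiplies expected traffic PM2.5 by
`exp(0.20) ≈ 1.22`, and sea-salt-reporting studies report about
`1 - exp(-0.40) ≈ 33%` lower traffic concentrations.

```r
rho <- posterior_correlation(fit)
#> correlation(traffic, overall): 0.55 (sd 0.11), 95% CI [0.32, 0.73]
max(gelman_rubin(fit)$rhat)
#> [1] 1.001

profs <- city_profiles(cur)
tab <- exceedance_curve(fit, profs, threshold = 5)
tab[c(1, nrow(tab)), c("city", "mean_overall", "mean_nontraffic",
                       "exceedance_probability")]
#>        city mean_overall mean_nontraffic exceedance_probability
#> 1  City_013         5.74            4.72                  0.357
#> 30 City_019        92.24           84.57                  1.000
```

The cleanest city (overall ≈ 5.7 µg/m³) has only a 36% chance of
remaining above the guideline without traffic; the most polluted one
exceeds it with certainty.

```r
ier  <- read.csv(fx[["ier"]])                # synthetic IER draws
pair <- counterfactual_pair(predict_city(fit, profs[nrow(profs), , drop = FALSE]))
city_paf_mc(pair, ier[ier$endpoint == "IHD", ])
#>       city endpoint age_group mean_paf_pct n_draws
#> 1 City_030      IHD     55-60          6.5    1000
```

Removing all traffic emissions in this city would avert an estimated
6.5% of IHD mortality (ages 55–60), averaged over 1000 IER parameter
draws.

The same pipeline runs from the shell:

```sh
inst/exec/trafficpm simulate --name small --dir fixtures
inst/exec/trafficpm run-all --records fixtures/small_records.csv \
    --ier-draws fixtures/small_ier_draws.csv --out results/run1 --seed 1
```

which writes the curated data, tidy posterior draws, diagnostics, the
per-city exceedance table, the city-by-endpoint PAF table and a JSON
run manifest.

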