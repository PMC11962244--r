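# phenodem

Phenology and demography inference for seasonal insect populations from
three complementary data sources:

* **Transect count surveys** — seasonal activity ("flight") curves are
  estimated with penalized-smooth count models of abundance against day of
  year (DOY) and year, `log(route length)` entering as an offset so that
  curves are expected counts per km:

  `y_i ~ Poisson(mu_i),  log mu_i = f(DOY_i, year_i) + log L_i`

  Candidate structures for `f` (DOY-only, additive, DOY x year
  interaction) are compared by manual likelihood-ratio tests and AIC.
  Each year's fitted curve yields *phenometrics*: dates and heights of the
  first, next-to-last and last peaks (the breeding generations), the area
  under the curve (abundance index), and the within-season growth ratios
  (next-to-last/first = "summer growth", last/first = "total growth").
  Year trends in each metric are tested by OLS, with confidence from a
  resample–refit–rederive bootstrap: the proportion of replicates with
  significant positive/negative trends plus a 16–84% percentile envelope.

* **Specimen records** — trends in the onset, median and end of a host
  plant's activity season are estimated by quantile regression of
  collection DOY on year at τ = 0.1, 0.5, 0.9, with an exact
  check-loss solver and Hall–Sheather sandwich standard errors.

* **Cohort experiments** — survival to eclosion in a caged larval-release
  design (sites × caged plants × earlier/current/later release timing) is
  modelled with a binomial-logit mixed model with a cage random intercept;
  development time with the analogous gaussian mixed model; cohort effects
  are tested with type II Wald chi-squared tests, and cohort means are
  back-transformed with confidence intervals (83.4% intervals make
  non-overlapping error bars a pairwise test at α = 0.05).

Synthetic-data generators (`simulate_surveys()`, `simulate_specimens()`,
`simulate_experiment()`) produce all three data kinds with recorded ground
truth, and drive the package's recovery and calibration tests.  See the
methods vignette (`vignettes/phenodem-methods.Rmd`) for model details and
design choices.

## Worked example

```r
library(phenodem)

# 17 years of weekday transect surveys with a +0.56 d/yr drift of the
# last generation pulse and declining within-season growth
surveys <- simulate_surveys(survey_sim_params(seed = 1))
sel <- model_selection_table(surveys, list(model_spec("doy_only"),
                                           model_spec("additive"),
                                           model_spec("interaction")))
sel
#> Seasonal model comparison
#>    structure  family  edf loglik  AIC winner
#>     doy_only poisson 13.2   -856 1739  FALSE
#>     additive poisson 14.2   -856 1740  FALSE
#>  interaction poisson 19.0   -833 1705   TRUE
#>
#> Likelihood-ratio tests
#>         full  reduced   chi2 edf_diff        p caveat_small_df
#>     additive doy_only  0.109    0.998 7.40e-01           FALSE
#>  interaction additive 45.498    4.809 9.06e-09           FALSE
#>  interaction doy_only 45.608    5.807 2.85e-08           FALSE
#>
#> Winning model: interaction
```

Abundance does not change additively across years (additive vs DOY-only:
p = 0.74), but phenology does (interaction vs additive: p < 1e-8) — the
injected year-by-season structure is detected.  The drift of the last
peak is then visible in the derived metrics:

```r
met <- annual_phenometrics(sel$fits[[sel$winner]])
fit_linear_trend(met$year, met$last_peak_doy, metric = "last_peak_doy")
#> Linear trend in last_peak_doy: slope = 0.674 /yr (SE 0.0289), t = 23.3, p = 3.39e-13, n = 17
```

(`bootstrap_trends()` quantifies the confidence in that slope by
refitting the winning model to resampled surveys; under these conditions
the positive last-peak trend is significant in essentially all
replicates.)  The cohort experiment (truths 0.008 / 0.095 / 0.048):

```r
surv <- fit_survival_glmm(simulate_experiment(experiment_sim_params(seed = 1)))
surv
#> Cohort survival model (binomial_glmm), cage random-intercept SD = 0.434
#>   cohort effect: Wald chi2 = 22.7, df = 2, p = 1.16e-05
#>   cohort estimate   lower  upper
#>  earlier   0.0109 0.00392 0.0299
#>  current   0.0913 0.05945 0.1376
#>    later   0.0529 0.02868 0.0955
```

and specimen quantile trends (injected drifts 0 / 0.25 / 0.5 days/yr):

```r
rep <- quantile_phenology_report(simulate_specimens(specimen_sim_params(
  n_per_year = 30, slopes = c(q10 = 0, q50 = 0.25, q90 = 0.5), seed = 1)))
rep
#> Quantile-regression phenology trends (days/yr)
#>  tau  label   slope     se     t        p    n
#>  0.1  onset -0.0968 0.0440 -2.20 2.80e-02 1470
#>  0.5 median  0.1538 0.0711  2.16 3.07e-02 1470
#>  0.9    end  0.4889 0.0509  9.60 3.36e-21 1470
```

The end-of-season drift (truth 0.5) is recovered at 0.49 ± 0.05; the
onset estimate illustrates ordinary sampling noise around its zero truth.
`run_pipeline(pipeline_config(...))` chains all stages and writes metric
CSVs, fit JSONs and a run manifest.

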