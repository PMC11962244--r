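Package: phenodem
Title: Phenology and Demography Inference from Count Surveys, Specimen
    Records and Cohort Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating seasonal activity (flight) curves from
    transect count surveys with penalized smooth count models and a survey
    effort offset; deriving per-year phenometrics (peak dates and heights,
    abundance index, within-season growth ratios) from the fitted curves;
    quantifying confidence in year trends of those metrics by a
    resample-refit-rederive bootstrap with sign-specific significance
    tallies and percentile envelopes; fitting quantile-regression trends to
    specimen collection dates at the 0.1, 0.5 and 0.9 quantiles; and
    analysing cage-structured cohort experiments with binomial-logit and
    gaussian mixed models.  Includes synthetic-data generators with
    recorded ground truth for all three data kinds, used for parameter
    recovery and calibration testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    lme4,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
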