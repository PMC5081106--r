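Package: diabtrends
Title: Hierarchical Bayesian Estimation of National Diabetes Prevalence Trends
Version: 0.1.0
Authors@R: person("NCD", "Modelling", email = "ncd.modelling@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating long-run national trends in adult diabetes
    prevalence from heterogeneous population-based survey data. Provides
    cross-walk regressions that harmonise prevalence measured under
    alternative biomarker definitions (2hOGTT, HbA1c, non-standard fasting
    glucose cutoffs, mean fasting glucose) to a single primary definition; a
    Bayesian hierarchical probit model with nested country/region/super-region
    levels and trends, non-linear time and age patterns, survey-scope bias
    terms and country covariates, fitted by MCMC; derived outputs including
    age-standardised and crude prevalence, case counts, a demographic
    decomposition of count changes, and the posterior probability of meeting
    the 2025 global diabetes target; hold-out validation utilities; and a
    synthetic-world generator that simulates survey datapoints with known
    ground truth so the whole pipeline can be exercised and validated without
    confidential survey microdata.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    jsonlite,
    yaml,
    rjags,
    coda,
    lme4
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
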