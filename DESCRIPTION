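Package: ordmrp
Title: Ordinal Multilevel Regression and Poststratification for Vaccination
    Intent Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian cumulative-logit multilevel regression and
    poststratification (MRP) for ordinal survey outcomes, with the net-shift
    impact statistics used to assess how vaccine-certification ("passport")
    policies move population-level COVID-19 vaccination inclination. Fits
    proportional-odds models with national fixed effects and region-level
    random deviations via Gibbs sampling (JAGS), composes a baseline-intent
    model and an intent-conditioned change-in-inclination model into a joint
    posterior-predictive distribution over census strata, and summarises it
    by per-intent-group net shifts U_k, their total S, and the
    domestic-minus-international contrast, each with 95% highest posterior
    density intervals. Includes a synthetic survey and census generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    rjags,
    coda,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
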