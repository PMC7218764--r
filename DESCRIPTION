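Package: rhdcea
Title: Cost-Utility Analysis of Echocardiographic Screening for Rheumatic Heart Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Markov cohort state-transition model for cost-utility analysis
    of one-time echocardiographic screening for rheumatic heart disease (RHD)
    in school-age children, compared with standard care. Provides a validated
    parameter-bundle format (health states, transition probabilities with
    uncertainty distributions, per-state annual costs, DALY weights, a life
    table and screening test characteristics), a cohort trace engine,
    discounted cost and DALY accrual with life-table years of life lost,
    ICER and net-monetary-benefit comparison, probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves, one-way (tornado)
    sensitivity analysis, external validation against observed age-band
    prevalences, and a synthetic parameter-bundle generator for testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
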