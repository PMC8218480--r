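Package: mspop
Title: Dynamic Multi-State Population Projection of Functional Disability
    and Cognitive Impairment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates annual health-state transition probabilities for older
    adults from two-wave panel surveys (midpoint imputation plus weighted
    multinomial logistic regression with age, sex and cognitive-impairment
    covariates and structural no-recovery constraints), quantifies their
    uncertainty with a survey-weighted resampling bootstrap, and feeds them
    into a deterministic cohort-component multi-state population model that
    projects the number of older adults with activity-of-daily-living
    limitations and cognitive impairment to 2060 under fertility-freeze,
    mortality-decline and transition-improvement assumption schedules.
    Includes a synthetic-cohort generator with known ground-truth transition
    kernels so that estimation, bootstrap and projection can be validated by
    parameter recovery without restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    nnet,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
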