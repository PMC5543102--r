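Package: mepmix
Title: Responder Stratification for Brain-Stimulation Studies by Gaussian
    Mixture Modeling and Computed ABC Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify responder subgroups in transcranial magnetic
    stimulation (TMS) plasticity studies from motor-evoked-potential (MEP)
    amplitudes. Implements trial-level preprocessing (artifact and first-trial
    exclusion, block averaging, baseline normalization), Pareto Density
    Estimation of the overall MEP-change distribution, one-dimensional Gaussian
    mixture modeling by expectation-maximization with likelihood-ratio model
    selection, Bayes-posterior decision boundaries for subgroup assignment,
    computed ABC analysis as an independent responder selector, confirmatory
    paired t-tests, and a synthetic trial-level cohort generator so the whole
    pipeline is testable without access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
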