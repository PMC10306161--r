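Package: ngsbia
Title: Hospital Budget Impact Modeling of Fast In-House NGS Testing in
    Metastatic Non-Small Cell Lung Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cohort-level health-economic model of introducing fast in-house
    next-generation sequencing (NGS) for metastatic non-small cell lung cancer
    from a US hospital budget perspective. A decision tree distributes each
    annual patient cohort across molecular-testing outcomes and therapy
    assignments; an eight-state Markov model with 30-day cycles propagates the
    cohorts over a five-year horizon; a budget engine converts test counts and
    state occupancy into discounted cost and revenue streams, return on
    investment, and the payback period. Includes probabilistic sensitivity
    analysis, one-way (tornado) sensitivity analysis, scenario sweeps,
    deterministic calibration of unreported parameters to published outputs,
    and a patient-level microsimulation that serves as an independent oracle
    for the cohort model. All results are returned as tibbles with broom-style
    tidiers and ggplot2 autoplot methods.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
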