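Package: endomol
Title: Molecular Classification, Cost Modelling and Survival Analysis for
    Endometrial Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for molecular subgroup classification of endometrial
    carcinoma from mismatch-repair and p53 immunohistochemistry and POLE
    hotspot sequencing, under the ProMisE and WHO cascade orders with DNA
    quality-control gating. Includes conventional and molecular-integrated
    adjuvant-therapy risk stratification, a deterministic direct-cost
    comparison of testing strategies, Kaplan-Meier and log-rank summaries,
    flexible parametric (Royston-Parmar) survival modelling with a
    confounder summary score, adjusted 5-year restricted mean survival
    times with bootstrap intervals, and a seeded synthetic cohort
    generator with piecewise-exponential survival for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    generics,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    yaml
Suggests:
    flexsurv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
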