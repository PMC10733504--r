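Package: deafscreenCEA
Title: Cost-Effectiveness Analysis of Pre-Pregnancy Genetic Screening for
    Deafness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness model of a two-step
    pre-pregnancy carrier screening programme for autosomal-recessive
    deafness (GJB2/SLC26A4). Implements a multi-payoff decision-tree engine
    with expected-value rollback, ICER and dominance comparison, three payoff
    models (deaf births averted, healthy births gained, lifetime cost-utility
    with discounted income and medical expenditure), one-way deterministic
    and threshold sensitivity analyses, probabilistic sensitivity analysis
    with cost-effectiveness acceptability curves and confidence ellipses, and
    an individual-level cohort microsimulation used as an independent
    validation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
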