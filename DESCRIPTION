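Package: pdrscreen
Title: Risk Factors for Proliferative Diabetic Retinopathy and Screening
    Economics in Young-Onset Type 1 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for case-control risk-factor analysis of proliferative
    diabetic retinopathy (PDR) in young-onset type 1 diabetes and for
    deterministic budget-impact modelling of a national retinopathy
    screening programme.  Provides a synthetic patient-cohort generator
    targeting published summary distributions, 2x2 contingency statistics
    (odds ratios with Woolf confidence intervals, continuity-corrected
    chi-square), Hodges-Lehmann shift estimation with Mann-Whitney tests,
    Lilliefors-based normality routing, a single-period screening cost
    model with break-even and one-way sensitivity analysis, and a small
    command-line pipeline tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
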