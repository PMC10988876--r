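Package: nitrial
Title: Design and Analysis Toolkit for a Non-Inferiority Trial of Acute Gout
    Treatment in Primary Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Planning and analysis tools for a multicenter, double-blind,
    1:1 randomized non-inferiority trial comparing prednisolone with
    colchicine for acute gout, with daily pain on a 0-10 numeric rating
    scale as the primary outcome. Provides exact noncentral-t sample-size
    and power calculations for the one-sided two-sample t-test framing of
    non-inferiority; per-center permuted block randomization with random
    block lengths and a complete-randomization comparator; simulation of
    treatment-arm imbalance under recruiting-center dropout and
    heterogeneous (zero-inflated Poisson) recruitment; a fully seeded
    synthetic patient-level trial generator; the statistical analysis plan
    engine (baseline-adjusted ANCOVA non-inferiority analysis, mixed-model
    and rank-based secondary analyses, logistic models, Holm-controlled
    subgroup interactions, Clopper-Pearson adverse-event summaries); and
    multiple imputation by chained equations with Rubin's-rules pooling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
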