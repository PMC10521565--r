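Package: cheineq
Title: Income-Related Inequality in Catastrophic Health Expenditure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for measuring and decomposing income-related inequality in
    catastrophic health expenditure (CHE) from household panel surveys. A
    household is flagged as incurring CHE when out-of-pocket health spending
    reaches 40 percent of its capacity to pay (non-food expenditure). The
    package computes per-wave CHE incidence with confidence intervals,
    weighted fractional income ranks, concentration curves and the
    covariance-form concentration index with analytic or bootstrap
    uncertainty, and decomposes the index into determinant contributions via
    probit average marginal effects. Robustness stages include pooled
    logistic regression odds ratios and quantile (pinball-loss) regression of
    household income on the CHE flag. A seeded synthetic household-panel
    generator emulating a balanced three-wave rural survey makes the full
    pipeline testable without restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
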