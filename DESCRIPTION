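Package: healthalloc
Title: Fairness and Efficiency of Regional Healthcare Resource Allocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for judging the fairness and the utilization efficiency of
    regional healthcare resource allocation from balanced province-by-year
    panel data. Implements population-weighted Theil index decomposition
    (overall, within-region and between-region inequality with contribution
    rates), input-oriented data envelopment analysis (CCR and BCC envelopment
    programs solved in two stages, efficiency decomposition TE = PTE x SE,
    returns-to-scale classification, and slack-based projection targets with
    input redundancy and output insufficiency rates), the Malmquist total
    factor productivity index with its efficiency-change / technical-change /
    pure-efficiency / scale-efficiency decomposition, and a right-censored
    Tobit regression of efficiency scores on development, resource-quantity
    and fairness covariates. A seeded synthetic panel generator with known
    ground truth (frontier inefficiency, inequality structure, regression
    coefficients) makes every stage verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
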