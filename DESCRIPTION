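Package: posdev
Title: Positive-Deviance Identification for Jurisdiction Health-Outcome Panels
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies positive deviants -- jurisdictions whose health
    outcomes are substantially better than a regression model predicts given
    their context -- in county-level panels such as local-health-department
    maternal-and-child-health data. Implements the full workflow: nested
    context and context-plus-mechanism ordinary least squares fits,
    likelihood-ratio model comparison, externally studentized residual
    thresholding, leverage and Cook's-distance influence diagnostics,
    correlated-covariate and parsimonious-model sensitivity analyses, and
    consolidation of per-(outcome, year) flags into a final positive-deviant
    set. Includes a synthetic panel generator with planted deviants and known
    ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
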