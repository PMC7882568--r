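Package: gcmm
Title: Parallel Multiple Mediation Models for Gambling Consumption Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the gambling consumption mediation model: an
    analysis pipeline from respondent-level gambling survey microdata
    (per-game-type frequency and usual spending, demographics, Problem
    Gambling Severity Index) through breadth/depth feature engineering,
    parallel multiple mediation models with percentile-bootstrap
    confidence intervals, cohort comparison statistics with effect
    sizes, and dominant-mediator profile classification. Includes a
    synthetic survey generator with plantable mediation paths for
    validation by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
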