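Package: rrstage
Title: Multi-Stage Randomized-Response Designs for Sensitive-Attribute Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, analysing and simulating multi-stage
    randomized-response (RR) surveys of a sensitive binary attribute. A
    j-stage randomizing device either presents the sensitive question at
    each stage or passes the respondent onward, ending in a Warner-style
    draw; the design enters all inference only through the product Q of the
    per-stage continuation probabilities. The package provides the unbiased
    prevalence estimator and its variance, an unbiased variance estimator,
    Wald intervals, the posterior-odds privacy-protection measure and its
    exact variance decomposition, efficiency-dominance comparisons between
    nested designs (including the Warner, Mangat-Singh and three-stage
    special cases), matched-design solving, grid and curve generators for
    efficiency surfaces, and a respondent-level Monte-Carlo simulator that
    validates the estimator theory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
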