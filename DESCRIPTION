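Package: isfmtrial
Title: Factorial Fertility-Trial Analysis with Partial-Budget Economics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the complete analysis chain of multi-season factorial
    randomized complete block (RCBD) fertility trials of the kind used to
    evaluate integrated soil fertility management in maize: agronomic unit and
    grain-moisture conversions, amendment production accounting (biochar,
    vermicompost, lime requirement from exchangeable acidity), combined-over-
    years fixed-effects ANOVA with LSD mean separation and compact letter
    display, trait correlation with significance classes, and CIMMYT-style
    partial-budget economics (dominance analysis, marginal rate of return, and
    recommendation against a minimum acceptable rate of return). A calibrated
    synthetic-trial generator reproduces the statistical structure of a
    two-season 3x3x3 nitrogen-phosphorus x biochar x vermicompost maize trial
    so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
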