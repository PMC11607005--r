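Package: menamort
Title: Name-Based MENA Ancestry Classification and Over-65 Mortality from
    Doubly Truncated Death Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the immigrant mortality advantage among
    Middle Eastern and North African (MENA) Americans in administrative
    death records. Provides a byte-pair-encoding tokenizer and a gated
    recurrent sequence classifier that scores the probability a full name
    is of MENA origin; a maximum-likelihood estimator for Gompertz
    proportional-hazard mortality models under double truncation (deaths
    observable only inside a calendar window and above an age floor), with
    hazard ratios, conditional life expectancy at 65 (e65), and nativity
    effects with confidence intervals; a synthetic person-record generator
    emulating social-security-style mortality files; and a pipeline that
    ties classification and mortality estimation together and emits the
    standard descriptive, hazard-ratio, and life-expectancy tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    glmnet,
    MASS,
    Matrix,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
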