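Package: cllscreen
Title: Ex Vivo Drug Sensitivity Screening Analysis for CLL
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for ex vivo drug-sensitivity screens of
    chronic lymphocytic leukemia (CLL) cells cultured in a tumor
    microenvironment model. Converts raw 384-well plate luminescence to
    control-anchored percent viability, computes Z'-factor plate quality
    control, fits four-parameter logistic concentration-response curves,
    and summarizes each curve as a drug sensitivity score (DSS) including
    a modified DSS3 without the top-asymptote logarithm correction.
    Also provides arcsinh-ratio transformation of phospho-flow median
    intensities, longitudinal screen comparison with Manhattan/Ward
    clustering, and a synthetic screen generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
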