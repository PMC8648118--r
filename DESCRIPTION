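Package: bilatpop
Title: Bilateral Arm Population Analysis for Premotor and Motor Cortex Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing bilateral motor cortical population recordings
    collected during unimanual instructed-delay reaching. Implements soft-normalized
    firing-rate preprocessing, single-unit modulation and arm-preference metrics,
    cross-validated principal-component dimensionality estimation (PRESS with
    leave-one-trial and leave-one-unit reconstruction), covariance alignment between
    task conditions, component-level dedicated/distributed structure analysis,
    cross-temporal linear discriminant decoding, and restricted-exchangeability
    permutation and bootstrap inference. Includes a synthetic-session generator
    with known ground truth for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    Matrix,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
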