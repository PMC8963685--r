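Package: tndnc
Title: Double Negative Control Estimation of Vaccine Effectiveness in
    Test-Negative Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates vaccine effectiveness from test-negative design
    samples that are subject to unmeasured confounding and
    outcome-dependent selection, using a pair of negative control
    variables. A treatment confounding bridge function is estimated from
    the test-negative controls by solving user-specified moment
    equations, plugged into a closed-form inverse-weighted estimator of
    the causal log risk ratio, and paired with joint sandwich
    (M-estimation) inference and Wald intervals for vaccine
    effectiveness. Includes effect-modification extensions, negative
    control diagnostics, comparison estimators (oracle bridge, oracle
    inverse probability weighting, logistic regression), calibrated
    synthetic data generators with latent-confounder truth, and a Monte
    Carlo study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
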