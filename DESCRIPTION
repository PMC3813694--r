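Package: robustisles
Title: Isles of Robustness for Harvest Control Rules Under Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delimiting regions of a fishery model's parameter
    space in which management goals are met despite uncertainty ("isles of
    robustness"). Provides a deterministic monthly-step age-structured
    multi-fleet simulator with an MSY-transition harvest control rule,
    Latin-hypercube exploration of a normalized uncertainty space,
    variance-decomposition sensitivity ranking of inputs, two-stage
    conditional-inference classification trees that separate robust from
    non-robust parameter boxes, tree-stability resampling, and an info-gap
    robustness-horizon estimator. Results are tidy tibbles with ggplot2
    autoplot methods.
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
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
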