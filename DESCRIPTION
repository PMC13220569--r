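Package: poststrat
Title: Poststratification as a G-Method: Weighting, Standardization, and
    Selection-Bias Diagnostics for Nonprobability Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for making population-level inferences from nonprobability
    samples by poststratification, presented through the causal-inference lens
    that links it to g-methods. Implements the two equivalent poststratification
    estimators (individual-level cell weighting and stratum-mean aggregation),
    saturated inverse-probability-weighting and standardization estimators of
    counterfactual means and the average treatment effect, a two-stage
    poststratify-then-standardize procedure for comparing exposure groups,
    assumption and weight diagnostics (positivity reports, covariate balance,
    Kish effective sample size), and a Monte-Carlo simulation laboratory with
    configurable selection mechanisms for studying when reweighting removes
    selection bias and when violations of conditional independence or
    consistency defeat it.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
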