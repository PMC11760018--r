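Package: csdews
Title: Critical Slowing Down Early-Warning Signals for Post-Extubation
    Vital-Sign Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects critical slowing down in high-frequency vital-sign
    time series recorded after removal of mechanical ventilation in
    paediatric intensive care. Implements sliding-window variance and
    lag-1 autocorrelation indicators, the autocorrelation-corrected
    (Hamed-Rao) Mann-Kendall trend test with Holm-Bonferroni correction,
    and cohort-level inference: proportion z-tests, Welch t-tests on
    Kendall tau coefficients, confusion metrics with a positive-tau ROC
    convention, and weighted logistic regression with Nagelkerke R2.
    Includes a synthetic cohort generator based on an Ornstein-Uhlenbeck
    model whose decay rate ramps toward zero ahead of a fold bifurcation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
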