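Package: anfisrisk
Title: Predictive Occupational Safety Risk Assessment with Adaptive
    Neuro-Fuzzy Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predictive occupational health and safety risk
    assessment on construction sites. Expert ratings of probability,
    severity, exposure and detectability on a five-level linguistic
    ladder are combined into a multiplicative risk magnitude, predicted
    with a from-scratch first-order Takagi-Sugeno adaptive neuro-fuzzy
    inference system (ANFIS) trained by hybrid least-squares/gradient
    learning, classified into evaluation bands with mandated actions
    (accept, mitigate, eliminate), and ranked. Includes model-quality
    metrics (RMSE, MAPE, R squared, Cronbach's alpha), a linear
    regression baseline, a synthetic expert-rating generator, and a
    bundled worked case-study dataset from a multi-site construction
    safety survey.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
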