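Package: expectmon
Title: Real-Time Changepoint Monitoring for Nonlinear Expectile Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequential (online) changepoint detection for nonlinear parametric
    regression models estimated by conditional expectiles (asymmetric least
    squares). The unknown parameters are fitted on a changepoint-free block of
    historical data by an iterative grid search; new observations are then
    monitored one by one with a normalized CUSUM-of-scores detector whose null
    distribution is the supremum of a weighted multivariate Wiener process.
    Includes built-in linear and Gompertz growth-curve models, Monte-Carlo
    simulation of the limit law and its critical values for both open-end and
    closed-end monitoring, data generators and drivers for level and power
    experiments, and a small command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
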