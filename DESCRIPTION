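Package: enosenet
Title: Electronic-Nose Simulation and Deep Time-Series Regression for
    Continuous Malodor Gas Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying regulated malodor gases from
    multichannel electronic-nose (gas sensor array) time series. Provides a
    configurable simulator of sensor-array recordings with realistic
    response/recovery dynamics, environmental coupling and short-term drift
    (baseline random walk and exposure carry-over); signal preprocessing
    (lag alignment, Kalman and Savitzky-Golay filtering, min-max scaling,
    sliding-window sample construction); time- and frequency-domain feature
    extraction; ensemble feature and sensor-channel ranking (Pearson, binned
    mutual information, random-forest importance, SVM-RFE, mean-rank
    aggregation); an encoder-decoder CNN/Bi-LSTM concentration regressor
    with DCT channel attention and an external trend/seasonal drift
    compensation branch, together with its ablations and five classical
    baseline regressors; and an RMSE/R-squared/correlation evaluation and
    benchmarking harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    ranger,
    xgboost,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
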