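Package: twinforecast
Title: Digital-Twin Forecasting of Clinical Trajectories Through a
    Text-Generation Channel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasts multivariate clinical trajectories from sparse,
    irregular electronic-health-record style longitudinal data by
    serializing each patient history into text, sampling completions from
    a generative language-model backend fine-tuned with an output-masked
    loss, and aggregating the sampled trajectories into a final forecast.
    Includes deterministic preprocessing (temporal binning by last
    observed value, two-step outlier filtering, stratified patient-level
    splitting, landmark example construction), a seeded synthetic cohort
    generator emulating sparse correlated lab panels with
    therapy-dependent dynamics, three backends (copy-forward echo, a tiny
    trainable causal transformer, and an external-model adapter), and the
    full evaluation suite: patient-nested MAE, scaled MAE, MASE, SMAPE,
    weighted Spearman correlation, reference-range and trend ROC AUCs,
    Kolmogorov-Smirnov distribution distance, and cross-variable
    correlation preservation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
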