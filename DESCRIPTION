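Package: asircast
Title: Interpretable BiLSTM-Attention Forecasting of Stratified Incidence Rates
Version: 0.1.0
Authors@R:
    person("ASIR", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forecasts age-standardized incidence rates (ASIR) across sex-age
    strata with a dual-pathway deep network: a stacked bidirectional LSTM with
    multi-scale multi-head temporal attention and group-specific output heads,
    fused with a linear residual pathway through a learnable convex weight.
    Hyperparameters are tuned by particle swarm optimization with linearly
    decaying inertia, and predictions are explained with exact and
    gradient-based Shapley attribution at global, stratified and local levels.
    Includes a synthetic panel generator emulating Global Burden of Disease
    style sex-age incidence panels, leakage-free standardization and sliding
    window supervised framing, and an end-to-end command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
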