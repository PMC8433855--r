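Package: respredict
Title: Respiratory Tumor Motion Prediction with Temporal Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts internal tumor position from external respiratory
    marker traces with a configurable ahead time, compensating the beam
    latency of tracking radiotherapy systems. Implements a causal dilated
    temporal convolutional network (TCN) with residual blocks, a stacked
    LSTM baseline, sliding-window supervised dataset construction,
    Adam-based training with full-factorial grid search, per-direction and
    3D RMSE evaluation against a no-prediction (lagged) baseline, and a
    seeded synthetic respiratory-motion generator for desk-scale
    experiments without clinical traces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
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
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
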