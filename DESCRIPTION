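Package: gaitcascade
Title: Hierarchical Cascade Classification of Gait Events from Smart-Insole Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects six walking-behaviour events (sitting, standing still,
    standing with imbalance, walking, running, stumbling) from 20-channel
    smart-insole telemetry (16 plantar pressure sensors, temperature, 3-axis
    acceleration) sampled at about 4 Hz. Provides telemetry ingestion and
    timestamp alignment, sliding-window tensor construction with stratified
    train/validation/test splits, a seeded synthetic gait simulator, small
    feed-forward/convolutional/recurrent binary classifiers trained with
    cross-entropy and early stopping, hyperparameter search (random and
    tree-structured Parzen estimator samplers) with a ranked model registry
    for sensor-failure fallback, hierarchical cascade inference with streaming
    prediction and risk alerts, and a full binary/multiclass evaluation suite
    (confusion metrics and rank-based AUC).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
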