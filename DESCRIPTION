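Package: attncrop
Title: Process-Style Crop Growth Simulation with Attention Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits and runs a process-style greenhouse crop growth simulator built
    entirely from attention networks: a shared multi-head attention encoder over
    hourly environment features (temperature, humidity, radiation, day/night
    temperature difference, daily cumulative radiation, cumulative growing degree
    days, vapour-pressure deficit) feeding six multitask decoders that predict
    grouped daily growth factors (status, property, leaf, stem, petiole, harvest).
    Includes feature engineering (GDD, SVP/VPD, DIF), sparse destructive-sampling
    label interpolation with stochastic augmentation, a consistency-constrained
    eight-term training loss, recursive daily simulation from initial state and
    environment only, Nash-Sutcliffe-style modeling-efficiency and NRMSE
    evaluation against a mean baseline, attention-weight and hidden-layer export,
    an ablation harness, and a synthetic greenhouse + reference-grower data
    generator so the full workflow runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
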