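Package: oiprdecode
Title: Pseudo-Population Decoding and Population Geometry for the
    Object-in-Place Reward Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for the object-in-place reward (OIPR) task,
    a fast-learning paradigm in which each of five scenes is bound to one of
    three reward sizes for a block of six runs. Provides behavioral
    statistics (learning curves against chance, stay/switch proportions,
    reaction-time comparisons), time-resolved pseudo-population decoding of
    reward size and stay/switch action with linear support-vector machines
    and label-shuffle null distributions, within-block sliding-trial-window
    decoding, balanced-sampling decoding that decorrelates confounded task
    variables, discriminant-projection analysis of population geometry with
    a distribution overlap index, and per-neuron variance partitioning
    between motor and reward regressors. A synthetic-data module generates
    task designs, agent behavior and Poisson spike trains with the same
    statistical structure, so the whole pipeline is testable end to end
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
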