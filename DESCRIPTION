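Package: meawell
Title: Multi-Well Multi-Electrode Array Spike-Train Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for multi-well multi-electrode array (MEA)
    recordings of spontaneously firing neuronal cultures. Provides a
    plain-text spike-event interchange format, high-noise event filtering
    and array-level firing-rate metrics, minimum-F bootstrap assignment of
    treatment cohorts, repeated-measures ANCOVA power simulation,
    unsupervised recording-independent spike sorting (waveform shape
    features, log-PCA embedding, Gaussian mean-shift clustering),
    functional-network inference with the spike time tiling coefficient
    and permutation nulls, gamma-GLM and nested mixed-effect phenotype
    models, and a synthetic plate simulator with ground truth for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    multcomp,
    nlme,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    cluster,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
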