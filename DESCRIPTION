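Package: calciumRF
Title: Receptive-Field Plasticity Analysis for Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying receptive-field plasticity
    of cerebellar Purkinje cell dendrites from two-photon calcium imaging.
    Covers rigid motion correction by whole-frame cross-correlation,
    percentile-baseline dF/F computation with moving-window smoothing,
    calcium-event detection with a topographic prominence criterion,
    response-window trial classification against a shuffled-window
    spontaneous null, pre/post-tetanus plasticity normalization with
    stimulus-intensity dependence classification, the cumulative-length /
    delta-length linescan statistic with hotspot and off-hotspot band
    metrics, the accompanying statistical battery (ANOVA with Tukey HSD,
    Kruskal-Wallis with Dunn-Sidak post hoc, compartment correlations), and
    a synthetic-session generator with ground truth so every stage is
    testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    car
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
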