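Package: tilscreen
Title: Scoring and Synergy Analysis for Compound Screens of T-Cell-Mediated Tumor Killing
Version: 1.0.0
Authors@R:
    person("J.", "Doe", email = "jdoe@example.com", role = c("aut", "cre"))
Description: Tools for analysing compound screens that look for enhancers of
    T-cell-mediated tumor killing. Implements the comboscore screen statistic
    on well-level cleaved-caspase-3 readouts with ranking and enhancer calls,
    Chou-Talalay median-effect fitting with combination-index and isobologram
    synergy analysis, cross-cell-line differential-expression gene ranking
    with a Kolmogorov-Smirnov-type gene-set enrichment statistic and
    permutation p-values, and 2^-ddCT relative qPCR quantification. Every
    pipeline stage has a matched seeded synthetic-data generator that emits
    ground truth, so the whole analysis is exercisable at desk scale with
    known answers. A single command-line entry point wires the stages
    together with machine-readable run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
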