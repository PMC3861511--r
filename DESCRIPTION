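Package: rdarray
Title: Relative-Distance Biomarker Selection for Multi-Gene qPCR Arrays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Replicate-level selection of biomarker genes and gene sets from
    grouped qRT-PCR array data. Implements the relative distance (RD) model:
    a directed, per-replicate Euclidean separability statistic that compares a
    replicate's mean distance to another treatment group against its mean
    distance to its own group, adjusted by the standard deviations of both.
    Provides 2^-ddCt normalization against the geometric mean of housekeeping
    genes, single-gene pairwise screening with the all-positive six-value
    discrimination rule, exhaustive and greedy search for gene sets that
    discriminate all treatment groups simultaneously, average-linkage cluster
    validation of selected sets, and a synthetic-data generator with planted
    discriminating genes for ground-truth testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, S4Vectors, SummarizedExperiment, ape
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
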