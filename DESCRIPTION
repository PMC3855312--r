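Package: cghstability
Title: Stability-Based Comparison of Class-Discovery Methods for DNA Copy-Number Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for choosing a class-discovery method (input representation,
    dissimilarity measure, clustering algorithm) for array-CGH copy-number
    profiles by measuring the stability of its partitions under subsampling.
    Implements minimal-region extraction from copy-number calls,
    copy-number-specific similarities (sim with diagonal correction, agree,
    conc), agglomerative, divisive, partitioning and total clustering,
    partition agreement coefficients (Jaccard, simple matching,
    Rogers-Tanimoto), resampling-based stability records, and an iterative
    chi-square homogeneity test (valid under dependent resamplings) with
    Bonferroni-Holm correction that declares a subset of methods stable.
    Includes a synthetic copy-number data generator with planted classes and
    a config-driven benchmark runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
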