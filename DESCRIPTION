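Package: zibench
Title: Simulation and Benchmarking of Differential Expression Tests for
    Sparse Metatranscriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating differential expression (DE) methods on
    sparse, zero-inflated gene-by-sample expression matrices such as those
    produced by metatranscriptomics pipelines. Provides parametric simulators
    for zero-inflated log-normal, negative-binomial and gamma data with a
    factorial disease/batch effect design; semi-parametric spike-in and
    permutation-null generators; native implementations of the log-normal,
    logistic-beta two-part, Kruskal-Wallis and two-part Kruskal-Wallis tests
    with batch stratification; Lilliefors-type goodness-of-fit testing; and a
    harness that scores any method for type I error, false discovery rate,
    sensitivity and accuracy against simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
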