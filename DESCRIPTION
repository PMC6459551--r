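Package: amvml
Title: Adaptive Multi-View Multi-Label Learning for miRNA-Disease
    Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts disease-associated candidate miRNAs by adaptively
    learning consensus affinity graphs for diseases and miRNAs from
    multiple similarity views and propagating known associations through
    both graphs via a graph-regularised multi-label model solved with a
    Sylvester equation.  Includes constructors for the standard input
    views (MeSH-DAG disease semantic similarity, miRNA sequence and
    functional similarity, Gaussian interaction profile kernels),
    cross-validation protocols (global leave-one-out, repeated k-fold,
    leave-one-disease-out, top-N temporal validation) with leakage-safe
    view rebuilding, and a seeded synthetic block-model benchmark
    generator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
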