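Package: coexnet
Title: Weighted Gene Co-Expression Networks, Module Detection and
    Cross-Condition Module Preservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted gene co-expression networks from two-condition
    time-course expression data (Pearson correlation, soft-threshold power
    adjacency, topological overlap), detects co-expression modules by
    average-linkage clustering of the topological-overlap dissimilarity with
    a dynamic tree cut, summarizes modules by eigengenes and kME module
    membership, quantifies cross-condition and stage-wise module preservation
    with permutation Zsummary statistics, and prioritizes intramodular hub
    genes. Includes a synthetic two-condition study generator with planted
    co-expression modules of graded membership and preservation so the whole
    pipeline is testable without microarray downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    mclust,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
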