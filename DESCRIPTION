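Package: mirmod
Title: Identification of miRNA-mRNA Regulatory Modules from Matched
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step discovery of many-to-many microRNA-mRNA regulatory
    modules. Step one clusters mRNAs and miRNAs from a binary
    target-prediction map matrix, either on Euclidean distances between
    binary target profiles (unguided) or on a multivariate random forest
    proximity that lets matched expression profiles guide the grouping
    (guided), and keeps clusters that are tighter than expected by chance
    under a non-parametric bootstrap. Step two scores every miRNA-cluster by
    mRNA-cluster pair by counting predicted pairs whose linear
    expression-change association is significant, tests the count against
    randomly drawn mRNA clusters, and reports cluster pairs that pass the
    bootstrap test and a majority-targeting filter as potentially regulatory
    modules. Includes a synthetic-data generator with planted modules for
    benchmarking, tidy() and glance() methods for all result objects,
    ggplot2 plotting, and a command-line pipeline.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
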