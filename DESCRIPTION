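Package: hubrep
Title: Multi-Level Reproducibility of Differential Co-Expression Signature Hubs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects signature hubs, highly connected proteins in a
    protein-protein interaction network whose average co-expression with
    their interaction partners differs between two phenotype groups, and
    quantifies the cross-study reproducibility of hub lists at four levels:
    direct protein overlap (PO score), interaction-neighbourhood topology
    (POT score, via hypergeometric neighbour-overlap tests), co-expression
    direction consistency (POT-e score, via a binomial sign test), and
    pathway enrichment overlap. Matched randomization null models
    (phenotype-label permutation, random protein lists, degree-preserving
    network rewiring) provide empirical significance for each score, and a
    synthetic-data generator with planted differential co-expression
    structure supports end-to-end validation.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
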