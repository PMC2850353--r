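Package: parsmix
Title: Maximum Parsimony for Mixed Molecular and Morphological Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Equally weighted maximum-parsimony analysis of mixed
    DNA/morphology/indel character matrices: a NEXUS reader and writer for
    mixed-datatype matrices with charset partitions, Fitch tree lengths with
    uncertainty- or polymorphism-style handling of multi-state cells,
    heuristic tree search by random stepwise addition plus tree
    bisection-reconnection (TBR) with minimum-branch-length collapsing,
    exhaustive search on small taxon sets, strict and majority-rule consensus,
    nonparametric bootstrap, Bremer support with partitioned and hidden branch
    support decompositions, ACCTRAN branch step counts, a random-outgroup
    rooting diagnostic for long-branch attraction, and a simulator for mixed
    matrices evolved on known trees so that every stage can be tested without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    ggplot2,
    generics,
    phangorn,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
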