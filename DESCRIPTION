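Package: clonetrace
Title: Clonal Tree Reconstruction from Time Course Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Maximum likelihood reconstruction of clonal evolutionary
    history from variant allele frequencies observed over a sequencing
    time course, as in long-term evolution experiments on bacterial
    populations. Implements exhaustive and greedy clonal tree searches
    with backtracking, permutation search over the unknown birth order of
    mutations that first appear at the same time point, constrained
    search using sequenced clone haplotypes, a clonal-expansion simulator
    with Dirichlet frequency drift, evaluation metrics, variant-calling
    filters for read-count tables, and Muller plot table export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
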