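Package: motifroles
Title: Motif-Role Fingerprints for Directed Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-node counting of the 30 node roles (orbits) of the 13
    connected three-node motifs of a directed network, in both the
    functional (partial subgraph) and structural (induced subgraph) sense.
    The two flavors are linked by exact unimodular integer conversion
    matrices derived from first principles, so structural statistics are
    obtained from an algebraic functional counting pass without triple
    enumeration. On top of the fingerprints the package computes directed
    clustering coefficients (total, in, out, middleman, cycle and
    3-feedforward subtypes), six directed transitivities plus the
    undirected transitivity, and in/out-degree-preserving null ensembles
    for role-overabundance screening of nodes, as used in the analysis of
    neuronal connectomes.
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
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
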