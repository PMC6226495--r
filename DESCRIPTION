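Package: cecanet
Title: Compositional Co-Occurrence Network Analysis of Cecal Microbiome Count Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers basis correlations between OTUs from sparse compositional
    16S count tables by log-ratio variance decomposition with Dirichlet
    resampling and permutation pseudo-p-values, builds signed co-occurrence
    networks, detects overlapping cohesive clusters on the positive subgraph
    by greedy cohesiveness growth, identifies polarizing hub ("keystone")
    taxa from the balance of positive and negative associations, mines
    frequent presence itemsets of OTUs, and compares alpha diversity between
    sample groups with permutation t-tests. Includes a synthetic community
    generator (log-normal basis abundances, multinomial counting) with
    planted correlation structure so every stage can be validated against
    known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    igraph,
    ape,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
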