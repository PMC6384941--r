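Package: netbiostrat
Title: Network-Based Biostratigraphy of Fossil Occurrence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds co-occurrence and bipartite networks (taxa, paleoenvironments,
    geologic formations) from fossil occurrence tables, partitions them into
    overlapping community units with a label-propagation algorithm (COPRA) scored
    by extended (overlap) modularity, tests community structure against
    degree-preserving null models and link-subsampling sensitivity analyses scored
    by normalized mutual information, and compares the resulting biozones with
    incidence-based rarefaction, extrapolation, and nonparametric richness
    estimators (Chao2, ICE, jackknife, bootstrap). Includes a synthetic occurrence
    generator with planted biozone and biotope structure for ground-truth recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    methods,
    vegan,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
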