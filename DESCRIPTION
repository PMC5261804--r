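Package: ppiess
Title: Protein-Protein Interaction Essentiality from Gene Knockdown Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers the essentiality of individual protein-protein
    interactions (PPIs) by combining pathway network topology with
    gene-level knockdown screens. A pathway superpathway is rewired per
    cell line using mutation, deletion and expression context, transformed
    into its dual (line) graph in which PPIs become nodes and shared
    proteins become edges weighted by an exponential kernel of protein
    essentiality, and a smoothed mass-propagation (weighted random walk)
    is iterated to a stationary PPI essentiality score in [0, 1], with an
    eigendecomposition closed form. Downstream screens include PPI versus
    maximum-partner-protein essentiality ratios (MPER), KS rank
    enrichment, drug-target enrichment with permutation FDR,
    mutation-stratified differential essentiality, and patient survival
    splitting by PPI presence with log-rank tests and Benjamini-Yekutieli
    correction. A seed-reproducible synthetic data generator emulates the
    screen, context, drug-sensitivity and survival inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    jsonlite
Config/testthat/edition: 3
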