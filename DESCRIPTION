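Package: netpharm
Title: Network Pharmacology Screening of Herb-Component-Target Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end network-pharmacology inference pipeline for
    multi-herb formulas: ADME-based bioactive-component screening (oral
    bioavailability and drug-likeness thresholds), assembly and
    intersection of formula-side and disease-side target sets,
    seed-expanded protein-protein interaction (PPI) subnetworks over a
    user-supplied background interactome, a two-stage topological
    core-target screen driven by six node-centrality statistics (degree,
    betweenness, closeness, eigenvector, local average connectivity, and
    summed edge-clustering-coefficient centrality), MCODE dense-module
    detection, and hypergeometric/EASE over-representation analysis with
    Bonferroni control. Includes synthetic-data generators with known
    ground truth for every input the pipeline consumes, so the whole
    chain is testable without any live database access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
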