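Package: coremod
Title: Network-Based Discovery of Mutated Core Modules from Expression and
    Interaction Data
Version: 0.1.0
Authors@R:
    person("Core Module", "Developers", email = "coremod@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate driver-mutation gene modules ("core
    modules") by combining gene expression, protein-protein interaction
    networks, Gene Ontology gene sets and somatic mutation catalogs.
    Gene Ontology sets are intersected with the measured genes and their
    interaction subgraphs are weighted by absolute co-expression; each
    weighted subgraph is partitioned into small functional modules with a
    size-capped weighted Girvan-Newman edge-betweenness algorithm; modules
    are ranked by a chi-square statistic on the quadratic sum of per-gene
    t scores (p-SAGE) and tested for somatic-mutation enrichment with
    Fisher's exact test. Core modules are the mutation-enriched members of
    the top-ranked set. Downstream tools compute network topology
    statistics (density, centralization, heterogeneity, clustering,
    closeness), cross-condition network relatedness, a neighbor-joining
    phylogeny of conditions, split-half reproducibility protocols with
    permutation controls, and a fully seeded synthetic-data generator with
    planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
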