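Package: mutgraph
Title: Mutational Graph Inference from Single-Cell and Multi-Region Binary
    Genotype Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers mutational graphs (trees, forests and restricted DAGs)
    describing the temporal order in which somatic alterations accumulate in
    a single tumour, from binary presence/absence matrices obtained by
    single-cell or multi-region bulk sequencing. Candidate orderings are
    screened by Suppes' probabilistic-causation conditions assessed with a
    nonparametric bootstrap and one-tailed Mann-Whitney tests; output models
    are fitted by optimum branching (Edmonds, Gabow) or maximum-weight
    spanning trees (Chow-Liu, Prim) directed by marginal frequencies.
    Includes a ground-truthed synthetic-data generator with asymmetric
    genotyping noise, EM-based multiple imputation of missing entries,
    bootstrap edge-confidence scores, hypergeometric overlap tests, and a
    simulation-study harness computing edge-level sensitivity and
    specificity.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: SomaticMutation, SingleCell, GraphAndNetwork, Phylogenetics
RoxygenNote: 7.3.3
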