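Package: nscnet
Title: Connectome and Paracrine Network Analysis of Insect Neurosecretory Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the synaptic and hormonal connectivity of
    neurosecretory cells (NSC) in the adult Drosophila brain from whole-brain
    connectome exports and single-cell expression matrices. Builds thresholded
    synaptic graphs from edge and annotation tables, clusters NSC by the cosine
    similarity of their presynaptic input profiles, traces mono-, di- and k-hop
    sensory-to-endocrine pathways with transmitter annotation, summarises strong
    and shared inputs and synaptic outputs, and infers putative paracrine
    ligand-receptor networks between NSC clusters and peripheral tissues from
    expression scores. Includes seeded synthetic connectome and expression
    generators with ground truth for end-to-end validation, and a pipeline
    orchestrator that writes a reproducible run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    mclust,
    ape,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
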