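Package: scPanelDesign
Title: Constrained Gene Panel Design for Single-Cell Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs gene panels of a fixed size d for targeted single-cell
    spatial transcriptomics assays by training a small multi-class neural
    classifier with a one-to-one feature-selection layer and a custom
    four-term regularizer (sparsity, panel-size, gene-priority and
    protein-complex pairing penalties). Includes the standard scRNA-seq
    preprocessing workflow the model consumes (filtering, total-count
    normalization, highly variable gene selection, covariate regression,
    scaling with clipping, per-type capping), a deterministic k-nearest
    neighbour evaluation protocol reporting accuracy and macro F1, a
    negative-binomial synthetic-data generator with planted markers,
    co-expression modules and complex pairs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    class,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
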