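Package: scSexBias
Title: Sex Bias in Cell Composition, Expression, and a Ribosomal-Protein
    Cell-Size Proxy for Sexed Single-Nucleus Atlases
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies sexual dimorphism in sexed single-nucleus RNA-seq
    atlases at the cell-type level. Computes per-cluster sex bias in cell
    numbers from replicate-normalized proportions with Wilcoxon testing and
    Benjamini-Hochberg correction, per-cluster per-gene sex bias in
    expression via pseudocounted log2 ratios and rank-sum z scores, and a
    ribosomal-protein gene-panel score used as a proxy for sex differences
    in cell size. Includes a negative-binomial synthetic atlas generator
    with known ground-truth biases, Leiden clustering with
    predominant-label annotation, loom/h5ad/MTX input, and the closed-form
    morphometry calculators (flight-muscle volume and nuclei extrapolation,
    cardiac fractional shortening and stroke volume, nucleolar ratios,
    qPCR delta-Cq fold changes) used for experimental validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SingleCellExperiment
Imports: methods, stats, utils, grDevices, Matrix, S4Vectors,
    SummarizedExperiment, BiocNeighbors, igraph, irlba, matrixStats,
    rhdf5, jsonlite, yaml, digest, ggplot2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
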