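Package: VEnCodeR
Title: Discovery and Quality Ranking of Intersectional Regulatory-Element
    Codes (VEnCodes) from CAGE-seq-Style Activity Matrices
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to discover, quality-rank, and cross-validate minimal
    combinations of k co-active regulatory elements (promoters and
    enhancers) that uniquely distinguish a target cell type from all other
    cell types in a regulatory-element-by-sample TPM activity matrix, as
    produced by CAGE-seq atlases such as FANTOM5. Implements conservative
    donor-aware binarization, random-sampling and greedy sparseness-ordered
    heuristic searches for exclusive "AND"-gate intersections (versatile
    entry codes, VEnCodes), Monte-Carlo false-negative robustness scoring
    (the E score), donor hold-out interindividual robustness (the z score),
    genomic-interval cross-validation against external regulatory-element
    call sets, pooling of single-cell activity profiles, and a synthetic
    landscape generator with planted ground-truth codes for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'expression-io.R'
    'binarize.R'
    'search.R'
    'robustness.R'
    'crossval.R'
    'single-cell.R'
    'synthetic.R'
    'cli.R'
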