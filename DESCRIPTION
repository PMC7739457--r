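Package: scDenseFly
Title: Fly-Inspired Locality-Sensitive Hashing for Single-Cell Expression Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locality-sensitive hashing for cell searching in single-cell
    RNA-seq data. Implements the SimHash, FlyHash and DenseFly binary
    encoders, a two-stage multi-probe Hamming-space search (short pseudo-hash
    candidate retrieval followed by long-hash refinement), a Gamma-Poisson
    count simulator with multiplicative batch effects and logistic dropout,
    and a Cohen's-kappa cross-validation harness for benchmarking cell-type
    identification across hash schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    withr,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
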