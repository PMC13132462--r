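Package: atacGDA
Title: scATAC-seq Cell Type Annotation via Sequence-Informed Embeddings
    and Graph Domain Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Intra-modality cell type annotation for single-cell ATAC-seq.
    Cells are embedded by training a network that reconstructs binary peak
    accessibility from k-mer embeddings of peak DNA sequences, taking the
    output-layer weight columns as cell embeddings. Unlabeled query (target)
    cells are then annotated by adversarial graph domain adaptation over
    k-nearest-neighbour cell graphs, combining a local graph convolution on
    the self-loop-normalised adjacency with a global convolution on a
    random-walk PPMI operator, fused by scaled dot-product attention and
    aligned across domains with a gradient-reversal domain discriminator.
    Includes a seeded synthetic-data generator (motif-structured peaks,
    class-specific accessibility, controllable batch effect) so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    methods,
    stats,
    utils,
    tools,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
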