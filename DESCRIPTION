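Package: grnlink
Title: Supervised Gene Regulatory Network Link Prediction from Single-Cell
    Expression with a Graph Convolutional Encoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers gene regulatory network (GRN) edges from single-cell
    RNA-seq expression and a partially known prior network of transcription
    factor (TF) to target-gene interactions, framed as supervised link
    prediction. Genes are embedded by a graph convolutional encoder that
    propagates log-normalized expression features over the symmetrically
    normalized prior network; candidate TF-target pairs are scored by a
    rectified dot-product decoder and the model is trained with a
    mean-squared-error loss against known edge labels, using hard negative
    sampling and validation-based checkpoint selection. Includes readers and
    writers for BEELINE-style expression and edge-list files, the standard
    highly-variable-gene preprocessing pipeline, ranking metrics (AUROC,
    AUPRC), and a synthetic planted-network generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
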