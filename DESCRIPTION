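Package: grnlink
Title: Gene Regulatory Network Inference by Contrastive Graph Attention Link Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers transcription-factor to target-gene regulatory interactions
    from a single-cell gene expression matrix and a partially observed prior
    network, framed as supervised link prediction on a bipartite TF-gene graph.
    A two-layer multi-head graph-attention encoder produces gene embeddings from
    two graph views (the observed network and a randomly edge-dropped copy); an
    inter-view InfoNCE contrastive loss aligns the views, and dual-view
    dot-product decoders with binary cross-entropy score candidate edges.
    Includes the train/validation/test split and negative-sampling protocols,
    few-shot transfer between cell lines via truncated-SVD feature alignment,
    edge-flip noise tooling, top-K edge ranking, and a planted-network
    simulator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
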