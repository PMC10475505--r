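Package: geneDR
Title: Gene-Path Message Passing for Drug Repurposing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts drug-disease associations on heterogeneous
    drug-gene-disease graphs by separating two message-passing strategies:
    an LSTM encoder with attention pooling that propagates information along
    random-walk-extracted gene paths into drug and disease nodes, and graph
    convolution on the drug-disease bigraph, alternated for two rounds on
    top of translation-based (TransE) initial embeddings. Includes a
    planted-module synthetic data generator, 5-fold cross-validation with
    1:1 negative sampling, AUPR/AUC/F1/Recall metrics, and the two ablation
    variants of the architecture (heterogeneous GCN without gene paths, and
    path-GCN instead of the LSTM encoder).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'hetgraph.R'
    'paths.R'
    'transe.R'
    'nn.R'
    'gcn.R'
    'gmp.R'
    'genedr.R'
    'evaluation.R'
    'synthetic.R'
    'reporting.R'
    'utils.R'
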