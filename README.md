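# geneDR

Drug repurposing by gene-path message passing on heterogeneous
drug–gene–disease graphs.

## The problem

Computational drug repurposing predicts new drug–disease associations from
a known association network. The pharmacological mechanism linking a drug
to a disease typically runs through a *chain* of genes — the drug binds a
protein, which perturbs interaction partners, which touch the disease's
pathology. Flat graph-convolutional message passing on the heterogeneous
graph mixes gene and drug/disease messages at every hop and needs many
layers to span a gene chain, at the cost of over-smoothing.

`geneDR` implements a two-strategy architecture that separates the two
kinds of message passing:

1. **Gene-path message passing (GMP).** Gene paths
   `anchor → g1 → g2 → …` (at most `L_max = 4` genes) are extracted per
   drug/disease anchor by random walk on the drug-gene / disease-gene /
   gene-gene (DGD) view, at most `K_max = 100` distinct paths per anchor.
   Each path is fed through an LSTM (genes first, anchor last) so the
   terminal hidden state accumulates the whole chain into the anchor; the
   paths of an anchor are pooled with trainable softmax attention
   `m_i = Σ_k a_k · LSTM(p_k)` and the anchor embedding is updated as
   `h_i ← tanh(W_u [h_i ‖ m_i] + b_u)`.
2. **Bigraph GCN.** The updated drug/disease embeddings are propagated on
   the drug–disease bigraph with a Kipf-style GCN,
   `H^(l) = act(D̃^(-1/2)(A+I)D̃^(-1/2) H^(l-1) W^(l))`, 3 layers.

The two strategies alternate for two rounds starting from TransE
embeddings trained on the DGD view (`‖h + r − t‖` translation scoring,
margin-ranking loss, typed negative corruption). Final drug and disease
embeddings are concatenated into a fully connected head,
`v(r,d) = σ(FC([h_r ‖ h_d]))`, trained with binary cross-entropy (Adam,
lr 0.001, hidden size 128 throughout).

Two ablation variants are built in: `no_gmp` (one flat heterogeneous GCN
over the combined drug-disease + DGD relations, no gene paths) and
`no_lstm` (the LSTM replaced by a single chain-GCN layer with mean pooling
over the path nodes). Evaluation follows 5-fold transductive
cross-validation with 1:1 negative sampling and AUPR / AUC / F1 / Recall.

All neural components (batched LSTM with backpropagation through time,
attention pooling, sparse GCN, predictor, Adam, TransE) are implemented in
base R + `Matrix`, with gradients verified against numerical
differentiation in the test suite.

## Worked example

The package ships a synthetic-data generator that plants the mechanism the
model is meant to exploit: genes fall into latent functional modules
(planted-partition gene-gene graph), each drug/disease anchors into its
module(s), and a drug–disease pair is associated iff the two share a
module — so associations are mediated by short gene paths by construction.

```r
library(geneDR)

sim <- generateSynthetic(synthConfig(seed = 7))
sim$graph
#> NodeRegistry with 100 nodes (20 drugs, 20 diseases, 60 genes)
#>   drug-disease    148 edges
#>   drug-gene        60 edges
#>   disease-gene     60 edges
#>   gene-gene       246 edges

## every true association is reachable through a <=4-gene path
expectedSignal(sim$truth, sim$graph)
#> [1] 1

cfg <- genedrConfig(hidden = 32, epochs = 150, K_max = 30, n_tries = 300,
                    transe_epochs = 300, patience = Inf, val_fraction = 0,
                    seed = 1)
cv <- crossValidate(sim$graph, cfg, folds = 0)   # train on folds 1-4, test on fold 0
round(cv$mean, 3)
#>   aupr    auc     f1 recall
#>  0.825  0.894  0.800  0.733
```

A held-out AUC of ~0.9 against a 0.5 chance baseline (1:1 negatives) means
the model recovers the planted module structure from paths, topology and
initial embeddings. `runAblationSuite()` repeats this per variant and
seed and tabulates the comparison.

A thin command-line front end is installed at
`system.file("scripts", "genedr", package = "geneDR")` with subcommands
`simulate`, `validate`, `embed`, `paths`, `train`, `predict`, `cv`,
`ablate`; all I/O is TSV/JSON/YAML (edge lists, dataset manifests,
embedding tables, JSON-lines path caches, results JSON).

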