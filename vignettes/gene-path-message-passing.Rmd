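---
title: "Gene-path message passing for drug repurposing: model, design choices and limitations"
author: "geneDR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-path message passing for drug repurposing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`geneDR` predicts drug–disease associations on a typed heterogeneous graph
with drug, disease and gene nodes and four undirected relations
(drug-disease, drug-gene, disease-gene, gene-gene). The premise is
mechanistic: a drug acts on a disease through a *chain* of genes, so the
signal that links a drug to a disease lives on gene paths, not on
individual edges. The architecture therefore separates two message-passing
strategies instead of running one flat GCN over the mixed graph:

1. **Initial embeddings.** TransE is trained on the DGD view (drug-gene,
   disease-gene, gene-gene; three relation embeddings), scoring a triple
   by `‖h + r − t‖` and minimizing margin-ranking loss against
   type-respecting uniformly corrupted negatives. Entity rows are
   L2-normalized after every update. This gives every node — including
   genes never touched by the supervised loss — a globally informed
   starting vector.
2. **Gene-path message passing (GMP).** Per anchor (drug or disease),
   random-walk paths of 1..`L_max` genes are encoded by an LSTM fed genes
   first and anchor last, so the terminal hidden state sits on the anchor
   and has absorbed the whole chain in mechanism order. An anchor's path
   encodings are pooled by softmax attention over a linear score of each
   encoding, and the anchor embedding is updated through a learned
   concatenation layer with tanh.
3. **Bigraph GCN.** The updated drug/disease rows are propagated on the
   drug–disease bigraph by a symmetric-normalized GCN with self-loops
   (ReLU between layers, linear last layer).
4. **Alternation and scoring.** Steps 2–3 alternate for two rounds; after
   each GCN the gene rows are reset to their TransE values, so round 2's
   path encoder reads fresh gene embeddings but round-1-refined anchor
   embeddings. Final drug and disease rows are concatenated into a
   one-hidden-layer fully connected head with a sigmoid output, trained
   with binary cross-entropy under Adam.

Two ablations share the pipeline: `no_gmp` replaces everything between
TransE and the predictor with a single flat 3-layer GCN over the combined
graph (all four relations); `no_lstm` keeps path extraction and attention
but encodes each path with one GCN layer on the path-as-chain adjacency
followed by mean pooling over the path nodes.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `hidden` | 128 | embedding/hidden width of TransE, LSTM, GCN and predictor (one width everywhere so messages compose) |
| `gcn_layers` | 3 | bigraph GCN depth |
| `lr` | 0.001 | Adam learning rate for the link model |
| `L_max` | 4 | maximum genes per path (the anchor is not counted) |
| `K_max` | 100 | maximum distinct paths kept per anchor |
| `n_tries` | `10 * K_max` | random walks attempted per anchor before capping |
| `rounds` | 2 | GMP→GCN alternations |
| `transe_lr`, `transe_margin` | 0.01, 1.0 | TransE SGD step and ranking margin |
| `k_folds` | 5 | cross-validation folds, 1:1 negative sampling |
| `threshold` | 0.5 | decision threshold for F1/Recall (the natural boundary of a sigmoid trained with cross-entropy) |

Walks forbid immediate backtracking (`g → g' → g`) but allow later
revisits: pure uniform walks on sparse gene graphs waste most of the
`K_max` budget on two-cycles. Path sets are extracted once before
training; `resample_per_epoch` was considered and rejected because a fixed
path set makes runs reproducible and testable, and the architecture
description extracts paths before the epoch loop. Deduplication happens
before capping: duplicate paths add no information under attention
pooling, so the cap buys `K_max` *distinct* mechanisms.

## Design choices where the design was open

- **Attention form.** Only "a trainable weight per path" is specified.
  A free parameter per path does not transfer across anchors or
  resampling, so the scorer is content-based: a linear functional of the
  path encoding, softmax-normalized per anchor. Weights are therefore
  trainable, nonnegative and sum to one.
- **Update function.** The update combining an anchor's previous state
  with its message is a learned linear layer on the concatenation with
  tanh — strictly more expressive than a sum and standard as a GNN update
  gate. Empty path sets yield a zero message, so such anchors pass only
  their own state through the update.
- **Round carry-over.** Only drug/disease rows are re-initialized between
  stages; gene rows re-enter each round at their TransE values. The
  alternative (letting GCN-transformed gene rows flow back) was rejected:
  genes do not sit on the bigraph, so their GCN transform is an artifact
  of self-loops, not information.
- **Loss and optimizer.** Binary cross-entropy with Adam; standard for
  probabilistic link prediction with balanced negatives. Early stopping
  monitors validation AUPR (patience 50, 10% validation split) when
  enabled.
- **Weight sharing.** The path encoder and GCN have separate weights per
  round by default (`share_gmp_weights` reuses one encoder).
- **`no_lstm` encoder.** "GCN along the path" is under-specified; the
  minimal faithful reading is one symmetric-normalized chain-adjacency
  GCN layer (tanh) followed by mean pooling over the path's nodes.
- **Predictor head.** One hidden layer of width `hidden` with ReLU;
  a single linear layer is available via `predictor_hidden = FALSE`.
- **Ids.** Node ids are global across the three types and contiguous
  `1..N`, so an id is literally the row of every embedding matrix.
- **TransE gradient scale.** Per-triple subgradients are summed, not
  averaged, within an epoch's full-batch update — the classic SGD scale;
  averaging makes the effective step vanish with the triple count and the
  embedding never leaves its initialization.
- **Gene-gene triples** take the smaller id as head; the translation
  asymmetry this induces is a known artifact of TransE on symmetric
  relations and is accepted.

## The synthetic generator

Real inputs at full scale (hundreds of drugs/diseases, tens of
thousands of genes, curated gene-gene relations) are external downloads,
so the package ships a generator that emulates their *structure*: genes
are partitioned into latent functional modules wired as a planted
partition (`p_intra = 0.35` within modules, `p_inter = 0.02` between),
each drug/disease draws one module (or a second with probability
`p_two_modules = 0.2`) and anchors onto `k_anchor = 3` member genes, and a
pair is truly associated iff the two entities share a module. A
`noise_rate = 0.05` fraction of pair labels is flipped; noise lives on
labels, not edges, so path extraction stays deterministic. The standard
study fixture uses 20 drugs, 20 diseases, 60 genes, 3 modules, seed 7.

`p_two_modules` stays below one half by design: module overlap drives the
positive rate, and with half the entities bi-functional, two thirds of all
pairs would be positive — leaving a negative pool smaller than the
positive set, which the 1:1 negative-sampling protocol cannot support.

`expectedSignal()` certifies a fixture before end-to-end use: the fraction
of true associations connected by a drug→gene(…gene)→disease path of at
most 4 genes must be at least 0.9 (it is 1.0 on the standard fixture).

What the generator does **not** emulate: PharmKG/CTD degree
distributions, curation biases, relation qualifiers (up/down-regulation),
or graphs where the gene signal is only reachable through long chains.
Passing end-to-end tests on this fixture shows the pipeline can recover
planted path-mediated structure; it does not certify performance on real
pharmacological networks.

## Numerical choices and degenerate inputs

- Sparse adjacency throughout (`Matrix`); the sparse GCN forward is tested
  against a dense oracle to 1e-5 on graphs up to 50 nodes.
- Softmax scores are max-shifted before exponentiation; attention weights
  sum to 1 within 1e-6.
- All analytic gradients (LSTM BPTT, chain-GCN encoder, attention,
  update, GCN, predictor) are verified against central differences at
  tolerance 1e-4 or better in the test suite.
- Anchors with no gene neighbors are legal: they get empty path lists and
  zero messages, and are reported by `validateDataset()`.
- Self-loop rows in input files are skipped with a warning; duplicate rows
  are silently deduplicated (multiplicity carries no meaning).
- Non-finite embeddings are rejected at module boundaries rather than
  propagated.
- A forward pass is invariant to the order of the scored pairs, and
  message pooling to the order of an anchor's paths (both tested at 1e-6).

## Problem sizes used in the shipped experiments

The packaged experiments (tests and `scripts/acceptance.R`) run the study
fixture with hidden width 32, `K_max = 30`, `n_tries = 300`, 150 fixed
epochs without early stopping, TransE for 300 epochs at d = 32, and one
held-out cross-validation fold per training seed with three training
seeds. These sizes are the package's choice of a desk-scale experiment on
a 100-node graph; the defaults (`hidden = 128`, `K_max = 100`, 5 folds,
early stopping) remain the full-scale reference settings.

## Known limitations

- On the planted-module fixture the three variants are statistically close
  (held-out AUC differences are within training-seed noise): every anchor
  has direct gene edges, so a flat 3-layer heterogeneous GCN already
  reaches the module signal through 2-hop drug–gene–disease paths. The
  advantage of path-based passing expected on real data — where flat
  passing must contend with huge, heterogeneous, hub-dominated gene
  graphs — is therefore not reliably reproduced at this scale, and the
  ablation-ordering check in the acceptance suite reflects that honestly.
- The TransE learning curve descends clearly but is not strictly monotone
  under a 10-epoch moving average: resampling corruption negatives every
  epoch leaves ~0.01–0.02 wobble at the loss plateau. This is inherent to
  margin SGD with stochastic negatives, not a convergence failure.
- Relations carry no qualifiers; an association and a side effect are
  indistinguishable to the model.
- Evaluation is transductive (edges hidden, nodes visible); cold-start
  prediction for unseen drugs is out of scope.
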