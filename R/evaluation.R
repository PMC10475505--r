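#' @include AllClasses.R hetgraph.R genedr.R
NULL

#' Build 5-fold cross-validation link samples with 1:1 negatives
#'
#' Positives (the drug-disease edges) are partitioned into `k` near-equal
#' folds; an equal number of negatives is sampled once, without
#' replacement, from the non-associated drug-disease pairs and assigned to
#' folds so every fold is balanced 1:1. Negative sets are disjoint across
#' folds and disjoint from the positives. Deterministic given `seed`.
#'
#' @param graph a [HeteroGraph-class].
#' @param k number of folds.
#' @param seed RNG seed.
#' @return data.frame with columns `drug`, `disease`, `label`, `fold`.
#' @export
makeFolds <- function(graph, k = 5L, seed = 1L) {
  pos <- relationEdges(graph, "drug-disease")
  stopIfNot(nrow(pos) >= k, sprintf("need at least %d positives for %d folds", k, k),
            class = "geneDRConfigError")
  drugs <- nodesOfType(graph, "drug"); diseases <- nodesOfType(graph, "disease")
  all_keys <- as.vector(outer(drugs, diseases, .pairKey))
  pos_keys <- .pairKey(pos[, 1L], pos[, 2L])
  neg_keys <- setdiff(all_keys, pos_keys)
  stopIfNot(length(neg_keys) >= nrow(pos),
            "negative pool smaller than the positive set", class = "geneDRSamplingError")
  withSeed(seed, {
    fold_pos <- sample(rep_len(seq_len(k) - 1L, nrow(pos)))
    neg_sel <- sample(neg_keys, nrow(pos))
    fold_neg <- fold_pos[sample.int(nrow(pos))]  # same fold-size profile
    np <- do.call(rbind, strsplit(neg_sel, ":", fixed = TRUE))
    data.frame(
      drug = c(pos[, 1L], as.integer(np[, 1L])),
      disease = c(pos[, 2L], as.integer(np[, 2L])),
      label = rep(c(1L, 0L), each = nrow(pos)),
      fold = c(fold_pos, fold_neg))
  })
}

#' AUPR, AUC, F1 and Recall of a score vector
#'
#' AUC is the rank statistic (concordance with 0.5 credit for ties); AUPR
#' integrates the precision-recall curve step-wise over the unique score
#' thresholds; F1 and Recall are taken at the decision threshold.
#'
#' @param scores numeric predictions.
#' @param labels binary labels.
#' @param threshold decision threshold for F1/Recall (score >= threshold is
#'   a predicted positive).
#' @return List with `aupr`, `auc`, `f1`, `recall`, `n_pos`, `n_neg`,
#'   `threshold`.
#' @export
computeMetrics <- function(scores, labels, threshold = 0.5) {
  stopIfNot(length(scores) == length(labels) && all(is.finite(scores)),
            "scores and labels must be finite and of equal length",
            class = "geneDRValidationError")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  stopIfNot(n_pos >= 1L && n_neg >= 1L, "metrics undefined for single-class labels",
            class = "geneDRMetricError")
  ## AUC via midranks: ties between a positive and a negative get 0.5
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ## AUPR: precision-recall points at each unique threshold, descending
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp_end <- cumsum(rle(s)$lengths)  # last index of each tied block
  tp <- cumsum(y)[grp_end]
  fp <- grp_end - tp
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  aupr <- sum(diff(c(0, rec)) * prec)
  ## thresholded metrics
  pred <- as.integer(scores >= threshold)
  tp_t <- sum(pred == 1L & labels == 1L)
  fp_t <- sum(pred == 1L & labels == 0L)
  fn_t <- sum(pred == 0L & labels == 1L)
  recall <- tp_t / n_pos
  precision <- if (tp_t + fp_t > 0L) tp_t / (tp_t + fp_t) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(aupr = aupr, auc = auc, f1 = f1, recall = recall,
       n_pos = n_pos, n_neg = n_neg, threshold = threshold)
}

#' k-fold cross-validation of a model variant
#'
#' Shares one TransE embedding and one path set across folds (both are
#' computed from the DGD view, which contains no drug-disease edges), then
#' per fold trains a fresh model on the training samples with a bigraph
#' adjacency built from training-fold positives only, and scores the
#' held-out fold.
#'
#' @param graph a [HeteroGraph-class].
#' @param config a [genedrConfig()].
#' @param folds which folds to evaluate (default all `config$k_folds`).
#' @param samples optional precomputed [makeFolds()] output.
#' @param Htranse,pathSet optional precomputed shared inputs.
#' @return List with `per_fold` (data.frame of the four metrics by fold),
#'   `mean`, `sd`, and the fold `samples`.
#' @export
crossValidate <- function(graph, config, folds = NULL, samples = NULL,
                          Htranse = NULL, pathSet = NULL) {
  k <- config$k_folds
  if (is.null(samples)) samples <- makeFolds(graph, k = k, seed = config$seed)
  if (is.null(folds)) folds <- sort(unique(samples$fold))
  dgd <- graphView(graph, "DGD")
  if (is.null(Htranse)) {
    st <- trainTransE(buildTripleSet(dgd), graph, d = config$hidden,
                      epochs = config$transe_epochs, lr = config$transe_lr,
                      margin = config$transe_margin, norm_order = config$transe_norm,
                      seed = config$seed)
    Htranse <- embeddingMatrix(st@entity, stage = "TransE")
  }
  if (is.null(pathSet) && config$variant != "no_gmp")
    pathSet <- extractGenePaths(dgd, L_max = config$L_max, K_max = config$K_max,
                                n_tries = config$n_tries, seed = config$seed)
  rows <- list()
  for (f in folds) {
    tr <- samples[samples$fold != f, , drop = FALSE]
    te <- samples[samples$fold == f, , drop = FALSE]
    model <- trainGeneDR(graph, tr, config, Htranse = Htranse, pathSet = pathSet)
    pos <- as.matrix(tr[tr$label == 1L, c("drug", "disease")])
    Ahat <- if (config$variant == "no_gmp") {
      e <- rbind(pos, relationEdges(graph, "drug-gene"),
                 relationEdges(graph, "disease-gene"), relationEdges(graph, "gene-gene"))
      normalizeAdjacency(e, n = nodeCount(graph))
    } else normalizeAdjacency(pos, n = nodeCount(graph))
    sc <- predictPairs(model, graph, Ahat, pathSet, Htranse,
                       as.matrix(te[, c("drug", "disease")]))
    m <- computeMetrics(sc, te$label, threshold = config$threshold)
    rows[[length(rows) + 1L]] <- data.frame(fold = f, aupr = m$aupr, auc = m$auc,
                                            f1 = m$f1, recall = m$recall)
  }
  per_fold <- do.call(rbind, rows)
  met <- c("aupr", "auc", "f1", "recall")
  list(per_fold = per_fold,
       mean = colMeans(per_fold[met]),
       sd = vapply(per_fold[met], stats::sd, 0),
       samples = samples)
}
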