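#' @include AllClasses.R nn.R paths.R
NULL

#' Initialize gene-based message-passing parameters
#'
#' Holds the path sequence encoder (an LSTM, or a single chain-GCN layer
#' for the `no_lstm` ablation), the linear attention scorer over path
#' encodings, and the anchor update layer
#' `h_i <- act(W_u [h_i || m_i] + b_u)`. Hidden size equals the embedding
#' dimension `d` so messages and embeddings compose.
#'
#' @param d embedding / hidden dimension.
#' @param encoder `"lstm"` or `"pgcn"` (chain-GCN path encoder).
#' @param activation update activation, `"tanh"` (default) or `"identity"`
#'   (used by structural tests).
#' @param seed RNG seed for the initialization.
#' @return Parameter list (`enc`, `w_att`, `Wu`, `bu`, `activation`).
#' @export
gmpParams <- function(d, encoder = c("lstm", "pgcn"), activation = "tanh", seed = 1L) {
  encoder <- match.arg(encoder)
  withSeed(seed, {
    list(enc = if (encoder == "lstm") lstmInit(d) else pgcnInit(d),
         w_att = drop(initW(d, 1L)),
         Wu = initW(2L * d, d), bu = numeric(d),
         activation = activation)
  })
}

## sequence fed to the encoder: genes in reverse walk order, anchor last,
## so the terminal hidden state sits on the drug/disease node.
.pathSeq <- function(anchor, genes) c(rev(genes), anchor)

#' Encode a single gene path
#'
#' Feeds the sequence (genes reversed, anchor last) through the encoder and
#' returns the terminal hidden state, which aggregates the whole path into
#' the anchor.
#'
#' @param params from [gmpParams()].
#' @param anchor anchor node id.
#' @param genes integer vector of gene ids (non-empty).
#' @param H embedding matrix ([EmbeddingMatrix-class] or plain matrix).
#' @return Numeric vector of length `d`.
#' @export
encodePath <- function(params, anchor, genes, H) {
  stopIfNot(length(genes) >= 1L, "cannot encode an empty path",
            class = "geneDRContractError")
  H <- embMatrix(H)
  ids <- .pathSeq(anchor, genes)
  Xs <- lapply(ids, function(i) H[i, , drop = FALSE])
  drop(encForward(params$enc, Xs)$E)
}

#' Attention-pool the messages of one anchor
#'
#' Path weights are `softmax` over a linear score of each path encoding;
#' the message is the weighted sum of encodings. An empty path list yields
#' the zero message.
#'
#' @param params from [gmpParams()].
#' @param anchor anchor id.
#' @param paths list of gene-id vectors.
#' @param H embedding matrix.
#' @return List with `message` (length-`d` vector), `weights` and
#'   `encodings` (one row per path).
#' @export
aggregateMessages <- function(params, anchor, paths, H) {
  H <- embMatrix(H)
  d <- ncol(H)
  if (!length(paths))
    return(list(message = numeric(d), weights = numeric(0),
                encodings = matrix(0, 0L, d)))
  E <- t(vapply(paths, function(p) encodePath(params, anchor, p, H), numeric(d)))
  s <- drop(E %*% params$w_att)
  a <- exp(s - max(s)); a <- a / sum(a)
  list(message = drop(crossprod(E, a)), weights = a, encodings = E)
}

## Batched forward over a whole path set. Groups paths by sequence length
## so each group is one encoder call over (B x d) step matrices.
## anchors: the drug/disease ids whose rows get updated (all of them, with
## zero message when they own no paths). Returns H' (+ cache).
gmpForwardCore <- function(params, pathSet, H, anchors, want_cache = FALSE) {
  d <- ncol(H)
  plist <- pathSet@paths
  p_anchor <- integer(0); p_genes <- list()
  for (a in names(plist)) {
    ps <- plist[[a]]
    if (length(ps)) {
      p_anchor <- c(p_anchor, rep(as.integer(a), length(ps)))
      p_genes <- c(p_genes, ps)
    }
  }
  P <- length(p_genes)
  E <- matrix(0, P, d)
  groups <- list()
  if (P) {
    lens <- vapply(p_genes, length, 0L) + 1L
    for (Tn in sort(unique(lens))) {
      sel <- which(lens == Tn)
      ids <- t(vapply(sel, function(k) .pathSeq(p_anchor[k], p_genes[[k]]),
                      integer(Tn)))
      if (Tn == 1L) ids <- matrix(ids, ncol = 1L)  # vapply degenerate shape
      Xs <- lapply(seq_len(Tn), function(t) H[ids[, t], , drop = FALSE])
      fw <- encForward(params$enc, Xs)
      E[sel, ] <- fw$E
      groups[[length(groups) + 1L]] <- list(sel = sel, ids = ids, cache = fw$cache)
    }
  }
  ## attention softmax per anchor
  attw <- numeric(P)
  if (P) {
    s <- drop(E %*% params$w_att)
    for (sp in split(seq_len(P), p_anchor)) {
      e <- exp(s[sp] - max(s[sp]))
      attw[sp] <- e / sum(e)
    }
  }
  ## messages per anchor (zero when no paths)
  M <- matrix(0, length(anchors), d)
  rownames(M) <- as.character(anchors)
  if (P) {
    msum <- rowsum(E * attw, group = p_anchor, reorder = FALSE)
    M[rownames(msum), ] <- msum
  }
  ## anchor update
  Xcat <- cbind(H[anchors, , drop = FALSE], M)
  Pre <- Xcat %*% params$Wu + rep(params$bu, each = length(anchors))
  Hnew <- if (identical(params$activation, "identity")) Pre else tanh(Pre)
  Hout <- H
  Hout[anchors, ] <- Hnew
  res <- list(H = Hout)
  if (want_cache)
    res$cache <- list(anchors = anchors, p_anchor = p_anchor, groups = groups,
                      E = E, attw = attw, Xcat = Xcat, Hnew = Hnew, n = nrow(H), d = d)
  res
}

## Backward through gmpForwardCore. dHout: gradient wrt H'. Returns
## list(grads, dH) where grads mirrors the numeric leaves of params.
gmpBackwardCore <- function(params, cache, dHout) {
  anchors <- cache$anchors
  d <- cache$d
  dH <- dHout
  dH[anchors, ] <- 0  # anchor rows of H' are produced by the update layer
  dHnew <- dHout[anchors, , drop = FALSE]
  dPre <- if (identical(params$activation, "identity")) dHnew
          else dHnew * (1 - cache$Hnew^2)
  dWu <- crossprod(cache$Xcat, dPre)
  dbu <- colSums(dPre)
  dXcat <- tcrossprod(dPre, params$Wu)
  dH <- scatterAdd(dH, anchors, dXcat[, seq_len(d), drop = FALSE])
  dM <- dXcat[, d + seq_len(d), drop = FALSE]
  rownames(dM) <- as.character(anchors)

  dw_att <- 0 * params$w_att
  dEncGrads <- encZeroGrads(params$enc)
  P <- length(cache$p_anchor)
  if (P) {
    E <- cache$E; attw <- cache$attw; p_anchor <- cache$p_anchor
    dMp <- dM[as.character(p_anchor), , drop = FALSE]  # per-path copy of its anchor's dM
    da <- rowSums(E * dMp)
    ds <- numeric(P)
    for (sp in split(seq_len(P), p_anchor)) {
      aa <- attw[sp]
      ds[sp] <- aa * (da[sp] - sum(aa * da[sp]))
    }
    dE <- attw * dMp + outer(ds, params$w_att)
    dw_att <- drop(crossprod(E, ds))
    for (g in cache$groups) {
      bw <- encBackward(params$enc, g$cache, dE[g$sel, , drop = FALSE])
      dEncGrads <- mapParams(`+`, dEncGrads, bw$grads)
      for (t in seq_len(ncol(g$ids)))
        dH <- scatterAdd(dH, g$ids[, t], bw$dXs[[t]])
    }
  }
  list(grads = list(enc = dEncGrads, w_att = dw_att, Wu = dWu, bu = dbu),
       dH = dH)
}

#' Gene-based message-passing update of an embedding matrix
#'
#' For every drug/disease anchor the attention-pooled message of its gene
#' paths is combined with its current embedding through the update layer;
#' gene rows pass through unchanged.
#'
#' @param params from [gmpParams()].
#' @param pathSet a [GenePathSet-class].
#' @param H an [EmbeddingMatrix-class] (or matrix) covering all nodes.
#' @param graph the [HeteroGraph-class] (identifies the anchor rows).
#' @return An [EmbeddingMatrix-class] with stage `"GMP"`.
#' @export
gmpUpdate <- function(params, pathSet, H, graph) {
  round_in <- if (is(H, "EmbeddingMatrix")) H@round else 0L
  M <- embMatrix(H)
  stopIfNot(all(is.finite(M)), "embedding matrix contains non-finite rows",
            class = "geneDRValidationError")
  anchors <- c(nodesOfType(graph, "drug"), nodesOfType(graph, "disease"))
  out <- gmpForwardCore(params, pathSet, M, anchors)
  embeddingMatrix(out$H, stage = "GMP", round = round_in + 1L)
}
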