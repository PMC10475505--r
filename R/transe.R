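#' @include AllClasses.R hetgraph.R
NULL

.TRIPLE_RELS <- c("drug-gene", "disease-gene", "gene-gene")

#' Build the triple set of the DGD view
#'
#' Each undirected DGD edge becomes exactly one (head, relation, tail)
#' triple in canonical orientation: the drug/disease is the head of
#' entity-gene relations; gene-gene edges take the smaller id as head. The
#' relation vocabulary has 3 entries (drug-gene, disease-gene, gene-gene).
#'
#' @param view the DGD [GraphView-class] (or a [HeteroGraph-class]).
#' @return Integer matrix with columns `head`, `rel` (1..3), `tail`.
#' @export
buildTripleSet <- function(view) {
  if (is(view, "GraphView"))
    stopIfNot(view@label == "DGD", "triples are built from the DGD view")
  out <- lapply(seq_along(.TRIPLE_RELS), function(r) {
    e <- relationEdges(view, .TRIPLE_RELS[r])
    if (!nrow(e)) return(cbind(head = integer(), rel = integer(), tail = integer()))
    cbind(head = e[, 1L], rel = r, tail = e[, 2L])
  })
  do.call(rbind, out)
}

.l2normalize <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  nrm[nrm == 0] <- 1
  M / nrm
}

#' Translation score of triples
#'
#' `||h + r - t||` under the state's norm; lower means more plausible.
#'
#' @param state a [TransEState-class].
#' @param triples integer matrix with columns head, rel, tail (a single
#'   triple may be given as a length-3 vector).
#' @return Numeric vector of nonnegative scores.
#' @export
transeScore <- function(state, triples) {
  if (is.null(dim(triples))) triples <- matrix(as.integer(triples), ncol = 3L)
  stopIfNot(all(triples[, c(1L, 3L)] >= 1L) && all(triples[, c(1L, 3L)] <= nrow(state@entity)),
            "triple refers to an unknown entity id", class = "geneDRIndexError")
  diff <- state@entity[triples[, 1L], , drop = FALSE] +
    state@relation[triples[, 2L], , drop = FALSE] -
    state@entity[triples[, 3L], , drop = FALSE]
  if (state@normOrder == 2L) sqrt(rowSums(diff^2)) else rowSums(abs(diff))
}

#' Train translation embeddings on a triple set
#'
#' Margin-ranking loss with uniformly corrupted head-or-tail negatives;
#' corruption is type-respecting (a corrupted entity is drawn from the
#' entities of the same node type as the one it replaces). Entity rows are
#' L2-normalized after every update. One full-batch gradient step per
#' epoch; deterministic given `seed`.
#'
#' @param triples triple matrix from [buildTripleSet()].
#' @param registry the [NodeRegistry-class] (or [HeteroGraph-class]) the
#'   ids refer to, used for typed corruption.
#' @param d embedding dimension.
#' @param epochs gradient epochs (0 returns the normalized random init).
#' @param lr learning rate.
#' @param margin ranking margin.
#' @param norm_order 1 or 2.
#' @param seed RNG seed.
#' @return A [TransEState-class] with the per-epoch mean loss trace.
#' @export
trainTransE <- function(triples, registry, d = 128L, epochs = 500L, lr = 0.01,
                        margin = 1, norm_order = 2L, seed = 1L) {
  if (is(registry, "HeteroGraph")) registry <- registry@registry
  n <- length(registry@name)
  stopIfNot(nrow(triples) >= 1L, "at least one triple required", class = "geneDRConfigError")
  stopIfNot(n >= 2L, "at least two entities required", class = "geneDRConfigError")
  type_pool <- lapply(.NODE_TYPES, function(tt) which(registry@type == tt))
  names(type_pool) <- .NODE_TYPES
  pool_size <- vapply(type_pool, length, 0L)
  head_ok <- pool_size[registry@type[triples[, 1L]]] >= 2L
  tail_ok <- pool_size[registry@type[triples[, 3L]]] >= 2L
  stopIfNot(all(head_ok | tail_ok),
            "cannot corrupt: some triple has a single entity of both endpoint types",
            class = "geneDRTrainingError")

  withSeed(seed, {
    E <- .l2normalize(matrix(stats::rnorm(n * d, sd = 0.1), n, d))
    R <- .l2normalize(matrix(stats::rnorm(3L * d, sd = 0.1), 3L, d))
    losses <- numeric(0)
    m <- nrow(triples)
    htype <- registry@type[triples[, 1L]]
    ttype <- registry@type[triples[, 3L]]
    for (ep in seq_len(epochs)) {
      ## corrupt head or tail uniformly (forced to the corruptible side
      ## when the other type has a singleton pool), same-type replacement
      corrupt_head <- stats::runif(m) < 0.5
      corrupt_head <- (corrupt_head | !tail_ok) & head_ok
      neg <- triples
      repl_type <- ifelse(corrupt_head, htype, ttype)
      repl <- vapply(repl_type, function(tt) {
        pool <- type_pool[[tt]]
        pool[sample.int(length(pool), 1L)]
      }, 0L)
      neg[corrupt_head, 1L] <- repl[corrupt_head]
      neg[!corrupt_head, 3L] <- repl[!corrupt_head]

      dpos <- E[triples[, 1L], , drop = FALSE] + R[triples[, 2L], , drop = FALSE] -
        E[triples[, 3L], , drop = FALSE]
      dneg <- E[neg[, 1L], , drop = FALSE] + R[neg[, 2L], , drop = FALSE] -
        E[neg[, 3L], , drop = FALSE]
      if (norm_order == 2L) {
        spos <- sqrt(rowSums(dpos^2)); sneg <- sqrt(rowSums(dneg^2))
      } else {
        spos <- rowSums(abs(dpos)); sneg <- rowSums(abs(dneg))
      }
      viol <- margin + spos - sneg > 0
      losses <- c(losses, mean(pmax(margin + spos - sneg, 0)))
      if (any(viol)) {
        ## (sub)gradient of the score wrt its difference vector; per-triple
        ## gradients are summed (classic SGD scale), not averaged, so the
        ## effective step does not vanish with the triple count
        gradOf <- function(diff, s) {
          if (norm_order == 2L) diff / pmax(s, 1e-12) else sign(diff)
        }
        gp <- gradOf(dpos[viol, , drop = FALSE], spos[viol])
        gn <- gradOf(dneg[viol, , drop = FALSE], sneg[viol])
        scale <- lr
        dE <- matrix(0, n, d); dR <- matrix(0, 3L, d)
        dE <- scatterAdd(dE, triples[viol, 1L], gp)
        dE <- scatterAdd(dE, triples[viol, 3L], -gp)
        dE <- scatterAdd(dE, neg[viol, 1L], -gn)
        dE <- scatterAdd(dE, neg[viol, 3L], gn)
        dR <- scatterAdd(dR, triples[viol, 2L], gp)
        dR <- scatterAdd(dR, neg[viol, 2L], -gn)
        E <- .l2normalize(E - scale * dE)
        R <- R - scale * dR
      }
    }
    new("TransEState", entity = E, relation = R, margin = margin,
        normOrder = as.integer(norm_order), loss = losses)
  })
}

#' Write / read an embedding matrix as TSV
#'
#' One row per node: node id, node name, then the `d` embedding values.
#'
#' @param emb an [EmbeddingMatrix-class], [TransEState-class] or matrix.
#' @param graph the graph providing node names.
#' @param path output path.
#' @return `path` invisibly (write); an [EmbeddingMatrix-class] (read).
#' @export
writeEmbedding <- function(emb, graph, path) {
  M <- if (is(emb, "TransEState")) emb@entity else embMatrix(emb)
  df <- data.frame(id = seq_len(nrow(M)), name = nodeName(graph, seq_len(nrow(M))), M)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEmbedding
#' @export
readEmbedding <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  M <- as.matrix(df[, -(1:2), drop = FALSE])
  dimnames(M) <- NULL
  embeddingMatrix(M[order(df$id), , drop = FALSE], stage = "TransE", round = 0L)
}
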