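# Independent oracles used against the package implementation. These are
# deliberately naive (exhaustive enumeration, O(n^2) scans, per-element
# recurrences) and never call the code paths they check.

# Exhaustive DFS enumeration of legal gene paths from an anchor: first a
# gene neighbor of the anchor, then gene-gene steps without immediate
# backtracking, up to L_max genes. Returns list of integer vectors (all
# prefixes are paths too, because a walk may stop early only when stuck;
# enumeration includes every reachable prefix since random walks of
# different lengths arise only from dead ends -- so we enumerate full
# trajectories: extend until L_max or no legal step).
enumeratePathsOracle <- function(graph, anchor, L_max = 4L) {
  rel <- if (nodeType(graph, anchor) == "drug") "drug-gene" else "disease-gene"
  out <- list()
  recurse <- function(path, prev) {
    cur <- path[length(path)]
    nb <- neighborsOf(graph, cur, "gene-gene")
    nb <- nb[nb != prev]
    if (length(path) == L_max || length(nb) == 0L) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (nxt in nb) recurse(c(path, nxt), cur)
  }
  for (g0 in neighborsOf(graph, anchor, rel)) recurse(g0, -1L)
  out
}

pathKey <- function(p) paste(p, collapse = ",")

# Hand BFS distance between two gene sets on the gene-gene relation,
# counting edges; Inf if unreachable.
bfsGeneDistOracle <- function(graph, sources, targets) {
  if (!length(sources) || !length(targets)) return(Inf)
  if (length(intersect(sources, targets))) return(0)
  dist <- rep(Inf, nodeCount(graph))
  dist[sources] <- 0
  frontier <- sources
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(unlist(lapply(frontier, neighborsOf, x = graph, relation = "gene-gene")))
    nxt <- nxt[is.infinite(dist[nxt])]
    if (!length(nxt)) return(Inf)
    dist[nxt] <- d
    if (length(intersect(nxt, targets))) return(d)
    frontier <- nxt
  }
  Inf
}

# Brute-force AUC: all positive-negative pairs, ties get half credit.
aucOracle <- function(scores, labels) {
  ps <- scores[labels == 1]
  ns <- scores[labels == 0]
  tot <- 0
  for (a in ps) for (b in ns) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ps) * length(ns))
}

# Brute-force AUPR: precision/recall computed from scratch at every unique
# threshold (descending), step-wise rectangle integration over recall.
auprOracle <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  area <- 0
  npos <- sum(labels == 1)
  for (t in ths) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / npos
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# Scalar-by-scalar LSTM recurrence for one sequence, hand implementation of
# the gate equations used as the oracle for encodePath.
lstmUnrollOracle <- function(Wx, Wh, b, xs) {
  d <- nrow(Wx)
  sig <- function(z) 1 / (1 + exp(-z))
  h <- numeric(d); cst <- numeric(d)
  for (x in xs) {
    z <- drop(x %*% Wx + h %*% Wh) + b
    i <- sig(z[1:d]); f <- sig(z[(d + 1):(2 * d)])
    o <- sig(z[(2 * d + 1):(3 * d)]); g <- tanh(z[(3 * d + 1):(4 * d)])
    cst <- f * cst + i * g
    h <- o * tanh(cst)
  }
  h
}

# Central-difference gradient of a scalar function of one numeric leaf.
numGrad <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
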