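#' @include AllClasses.R hetgraph.R
NULL

#' One random gene-path walk from an anchor
#'
#' The walk starts at a drug or disease anchor, steps uniformly to one of
#' its gene neighbors, then moves along gene-gene edges, choosing uniformly
#' among the current gene's neighbors excluding the gene it just came from
#' (no immediate backtracking). It stops after `L_max` genes or when no
#' legal step remains. Uses the current RNG state; seed via the caller.
#'
#' @param view the DGD [GraphView-class].
#' @param anchor drug or disease node id.
#' @param L_max maximum number of genes in the path.
#' @return Integer vector of gene ids (possibly length 0 if the anchor has
#'   no gene neighbors).
#' @export
walkOne <- function(view, anchor, L_max = 4L) {
  g <- view@parent
  atype <- nodeType(g, anchor)
  stopIfNot(atype %in% c("drug", "disease"),
            sprintf("walk anchor must be a drug or disease, got '%s'", atype),
            class = "geneDRTypeConflict")
  rel <- if (atype == "drug") "drug-gene" else "disease-gene"
  first <- neighborsOf(g, anchor, rel)
  if (!length(first)) return(integer())
  cur <- first[sample.int(length(first), 1L)]
  path <- cur
  prev <- -1L
  while (length(path) < L_max) {
    nb <- neighborsOf(g, cur, "gene-gene")
    nb <- nb[nb != prev]
    if (!length(nb)) break
    nxt <- nb[sample.int(length(nb), 1L)]
    prev <- cur
    cur <- nxt
    path <- c(path, cur)
  }
  path
}

#' Extract gene paths for a set of anchors by random walk
#'
#' For each anchor, up to `n_tries` walks are run, duplicates removed, and
#' at most `K_max` distinct paths kept (in order of first discovery).
#' Anchors with no gene neighbors get an empty entry. Deterministic given
#' `seed`.
#'
#' @param view the DGD [GraphView-class].
#' @param anchors drug/disease ids; defaults to all of them.
#' @param L_max maximum genes per path.
#' @param K_max maximum distinct paths per anchor.
#' @param n_tries walks attempted per anchor (default `10 * K_max`).
#' @param seed RNG seed.
#' @return A [GenePathSet-class].
#' @export
extractGenePaths <- function(view, anchors = NULL, L_max = 4L, K_max = 100L,
                             n_tries = 10L * K_max, seed = 1L) {
  stopIfNot(L_max >= 1L && K_max >= 1L, "L_max and K_max must be >= 1",
            class = "geneDRConfigError")
  g <- view@parent
  if (is.null(anchors)) anchors <- c(nodesOfType(g, "drug"), nodesOfType(g, "disease"))
  stopIfNot(all(nodeType(g, anchors) %in% c("drug", "disease")),
            "anchors must be drug or disease nodes", class = "geneDRTypeConflict")
  withSeed(seed, {
    paths <- vector("list", length(anchors))
    names(paths) <- as.character(anchors)
    for (i in seq_along(anchors)) {
      seen <- character()
      acc <- list()
      for (t in seq_len(n_tries)) {
        p <- walkOne(view, anchors[i], L_max)
        if (!length(p)) break  # no gene neighbors: every retry is identical
        key <- paste(p, collapse = ",")
        if (!key %in% seen) {
          seen <- c(seen, key)
          acc[[length(acc) + 1L]] <- p
          if (length(acc) >= K_max) break
        }
      }
      paths[[i]] <- acc
    }
    new("GenePathSet", paths = paths, LMax = as.integer(L_max), KMax = as.integer(K_max))
  })
}

#' Check the structural invariant of one gene path
#'
#' `genes[1]` must be a gene neighbor of the anchor under the anchor-typed
#' relation, consecutive genes must be gene-gene edges, all nodes must be
#' genes, and the length must not exceed `L_max`.
#'
#' @param graph a [HeteroGraph-class].
#' @param anchor anchor id.
#' @param genes integer vector of gene ids.
#' @param L_max maximum length.
#' @return `TRUE` or a character description of the violation.
#' @export
validGenePath <- function(graph, anchor, genes, L_max = 4L) {
  if (length(genes) < 1L) return("empty path")
  if (length(genes) > L_max) return("path longer than L_max")
  if (!all(nodeType(graph, genes) == "gene")) return("non-gene node in path")
  atype <- nodeType(graph, anchor)
  rel <- if (atype == "drug") "drug-gene" else "disease-gene"
  if (!genes[1L] %in% neighborsOf(graph, anchor, rel))
    return("first gene not adjacent to anchor")
  if (length(genes) > 1L)
    for (k in seq_len(length(genes) - 1L))
      if (!genes[k + 1L] %in% neighborsOf(graph, genes[k], "gene-gene"))
        return(sprintf("genes %d and %d not adjacent", genes[k], genes[k + 1L]))
  TRUE
}

#' Paths of one anchor
#'
#' @param pathSet a [GenePathSet-class].
#' @param anchor anchor id.
#' @return List of integer gene-id vectors.
#' @export
anchorPaths <- function(pathSet, anchor) {
  p <- pathSet@paths[[as.character(anchor)]]
  if (is.null(p)) list() else p
}

#' Write / read a path set as JSON lines
#'
#' One line per anchor-path pair: `{"anchor": id, "genes": [ids...]}`.
#'
#' @param pathSet a [GenePathSet-class].
#' @param path file path.
#' @return `path` invisibly (write); a [GenePathSet-class] (read).
#' @export
writePathSet <- function(pathSet, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('{"LMax": %d, "KMax": %d}', pathSet@LMax, pathSet@KMax), con)
  for (a in names(pathSet@paths)) {
    ps <- pathSet@paths[[a]]
    if (!length(ps)) {
      writeLines(sprintf('{"anchor": %s, "genes": []}', a), con)
    } else {
      for (p in ps)
        writeLines(sprintf('{"anchor": %s, "genes": [%s]}', a, paste(p, collapse = ",")), con)
    }
  }
  invisible(path)
}

#' @rdname writePathSet
#' @export
readPathSet <- function(path) {
  lines <- readLines(path)
  head <- jsonlite::fromJSON(lines[1L])
  recs <- lapply(lines[-1L], jsonlite::fromJSON)
  anchors <- vapply(recs, function(r) as.integer(r$anchor), 0L)
  paths <- list()
  for (a in unique(anchors)) paths[[as.character(a)]] <- list()
  for (r in recs) {
    a <- as.character(r$anchor)
    if (length(r$genes)) paths[[a]][[length(paths[[a]]) + 1L]] <- as.integer(r$genes)
  }
  new("GenePathSet", paths = paths, LMax = as.integer(head$LMax), KMax = as.integer(head$KMax))
}
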