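#' @include AllClasses.R
NULL

## ---- registry -----------------------------------------------------------

#' Number of nodes in a registry or graph
#'
#' @param x a [NodeRegistry-class], [HeteroGraph-class] or [GraphView-class].
#' @return Integer node count.
#' @export
nodeCount <- function(x) {
  if (is(x, "HeteroGraph")) x <- x@registry
  if (is(x, "GraphView")) x <- x@parent@registry
  length(x@name)
}

#' Node ids of one type
#'
#' @param x registry, graph or view.
#' @param type `"drug"`, `"disease"` or `"gene"`.
#' @return Integer vector of node ids.
#' @export
nodesOfType <- function(x, type) {
  if (is(x, "HeteroGraph")) x <- x@registry
  if (is(x, "GraphView")) x <- x@parent@registry
  which(x@type == type)
}

#' Node type / name lookup
#'
#' @param x registry or graph.
#' @param id integer node id(s).
#' @return Character vector.
#' @export
nodeType <- function(x, id) {
  if (is(x, "HeteroGraph")) x <- x@registry
  x@type[id]
}

#' @rdname nodeType
#' @export
nodeName <- function(x, id) {
  if (is(x, "HeteroGraph")) x <- x@registry
  x@name[id]
}

#' Look up node ids by name
#'
#' @param x registry or graph.
#' @param name character vector of node names.
#' @return Integer ids (`NA` where absent).
#' @export
nodeId <- function(x, name) {
  if (is(x, "HeteroGraph")) x <- x@registry
  match(name, x@name)
}

#' Register nodes under a type
#'
#' Names already registered under the same type are kept; a name already
#' registered under a different type is a type-conflict error.
#'
#' @param registry a [NodeRegistry-class].
#' @param names character vector of node names.
#' @param type node type for all of `names`.
#' @return The extended registry.
#' @export
addNodes <- function(registry, names, type) {
  stopIfNot(type %in% .NODE_TYPES, sprintf("unknown node type '%s'", type))
  names <- unique(as.character(names))
  hit <- match(names, registry@name)
  clash <- which(!is.na(hit) & registry@type[hit] != type)
  stopIfNot(length(clash) == 0L,
            sprintf("name '%s' already registered as type '%s', cannot re-register as '%s'",
                    names[clash[1L]], registry@type[hit[clash[1L]]], type),
            class = "geneDRTypeConflict")
  newn <- names[is.na(hit)]
  initialize(registry,
             name = c(registry@name, newn),
             type = c(registry@type, rep(type, length(newn))))
}

## ---- edge-list I/O ------------------------------------------------------

.canonEdges <- function(from, to, relation) {
  if (relation == "gene-gene") {
    lo <- pmin(from, to); hi <- pmax(from, to)
    from <- lo; to <- hi
  }
  e <- cbind(from, to)
  e <- e[!duplicated(paste(from, to)), , drop = FALSE]
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

.HEADER_TOKENS <- c("source", "target", "from", "to", "head", "tail",
                    "drug", "disease", "gene", "gene1", "gene2", "node1", "node2")

#' Read an edge-list TSV for one relation
#'
#' Accepts 2-column (or wider; extra columns ignored) tab-separated name
#' pairs; `#`-prefixed comment lines and an optional header line are
#' skipped. Rows are deduplicated; self-loop rows are skipped with a
#' warning; names are registered with the endpoint types the relation
#' demands.
#'
#' @param path file path.
#' @param relation one of [relationNames()].
#' @param registry a [NodeRegistry-class] to extend.
#' @return List with `edges` (canonical 2-column id matrix) and the extended
#'   `registry`.
#' @export
loadEdgeList <- function(path, relation, registry = nodeRegistry()) {
  stopIfNot(relation %in% .RELATIONS, sprintf("unknown relation '%s'", relation))
  stopIfNot(file.exists(path), sprintf("edge-list file not found: %s", path),
            class = "geneDRIOError")
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(list(edges = .canonEdges(integer(), integer(), relation), registry = registry))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 2L)
  stopIfNot(length(bad) == 0L,
            sprintf("malformed line %d in %s: expected >= 2 tab-separated fields",
                    lineno[bad[1L]], path),
            class = "geneDRParseError")
  a <- trimws(vapply(parts, `[[`, "", 1L))
  b <- trimws(vapply(parts, `[[`, "", 2L))
  stopIfNot(all(nzchar(a)) && all(nzchar(b)),
            sprintf("malformed line %d in %s: empty field", lineno[which(!nzchar(a) | !nzchar(b))[1L]], path),
            class = "geneDRParseError")
  if (tolower(a[1L]) %in% .HEADER_TOKENS && tolower(b[1L]) %in% .HEADER_TOKENS) {
    a <- a[-1L]; b <- b[-1L]
  }
  self <- a == b
  if (any(self)) {
    warning(sprintf("%d self-loop row(s) skipped in %s", sum(self), path))
    a <- a[!self]; b <- b[!self]
  }
  tt <- .REL_TYPES[[relation]]
  registry <- addNodes(registry, a, tt[1L])
  registry <- addNodes(registry, b, tt[2L])
  list(edges = .canonEdges(nodeId(registry, a), nodeId(registry, b), relation),
       registry = registry)
}

#' Write an edge list TSV
#'
#' Writes canonical deduplicated name pairs, one per line, tab-separated.
#'
#' @param graph a [HeteroGraph-class].
#' @param relation relation name.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(graph, relation, path) {
  e <- graph@edges[[relation]]
  writeLines(paste(nodeName(graph, e[, 1L]), nodeName(graph, e[, 2L]), sep = "\t"), path)
  invisible(path)
}

## ---- graph construction -------------------------------------------------

#' Build a HeteroGraph from per-relation edge id sets
#'
#' @param registry a [NodeRegistry-class] covering all endpoints.
#' @param edges named list (subset of [relationNames()]) of 2-column integer
#'   id matrices; missing relations default to empty.
#' @return A validated [HeteroGraph-class] with symmetric adjacency lists.
#' @export
buildHeteroGraph <- function(registry, edges = list()) {
  full <- setNames(vector("list", 4L), .RELATIONS)
  for (rel in .RELATIONS) {
    e <- edges[[rel]]
    if (is.null(e)) e <- cbind(integer(), integer())
    e <- matrix(as.integer(e), ncol = 2L)
    tt <- .REL_TYPES[[rel]]
    if (nrow(e)) {
      ok <- registry@type[e[, 1L]] == tt[1L] & registry@type[e[, 2L]] == tt[2L]
      stopIfNot(all(ok),
                sprintf("%s edge (%s, %s): endpoint type mismatch", rel,
                        registry@name[e[which(!ok)[1L], 1L]],
                        registry@name[e[which(!ok)[1L], 2L]]),
                class = "geneDRTypeConflict")
    }
    full[[rel]] <- .canonEdges(e[, 1L], e[, 2L], rel)
  }
  n <- length(registry@name)
  adj <- lapply(full, function(e) {
    nb <- vector("list", n)
    if (nrow(e)) {
      sp <- split(c(e[, 2L], e[, 1L]), c(e[, 1L], e[, 2L]))
      nb[as.integer(names(sp))] <- lapply(sp, function(v) sort(as.integer(v)))
    }
    nb[vapply(nb, is.null, TRUE)] <- list(integer())
    nb
  })
  new("HeteroGraph", registry = registry, edges = full, adjacency = adj)
}

#' Neighbors of a node under one relation
#'
#' @param x a [HeteroGraph-class] or [GraphView-class].
#' @param id node id.
#' @param relation relation name; for a view, defaults to all included
#'   relations (union of neighbors).
#' @return Sorted integer vector of neighbor ids.
#' @export
neighborsOf <- function(x, id, relation = NULL) {
  if (is(x, "GraphView")) {
    rels <- if (is.null(relation)) x@relations else relation
    stopIfNot(all(rels %in% x@relations), "relation not included in this view")
    return(sort(unique(unlist(lapply(x@parent@adjacency[rels], `[[`, id)))))
  }
  stopIfNot(relation %in% .RELATIONS, "unknown relation")
  x@adjacency[[relation]][[id]]
}

#' Per-relation degree
#'
#' @inheritParams neighborsOf
#' @return Integer degree.
#' @export
nodeDegree <- function(x, id, relation = NULL) length(neighborsOf(x, id, relation))

#' Edge count of a graph or view
#'
#' @param x graph or view.
#' @param relation optional single relation.
#' @return Integer.
#' @export
edgeCount <- function(x, relation = NULL) {
  if (is(x, "GraphView")) {
    rels <- if (is.null(relation)) x@relations else relation
    return(sum(vapply(x@parent@edges[rels], nrow, 0L)))
  }
  rels <- if (is.null(relation)) .RELATIONS else relation
  sum(vapply(x@edges[rels], nrow, 0L))
}

#' Edges of one relation (id matrix)
#'
#' @param x graph or view.
#' @param relation relation name.
#' @return 2-column integer matrix in canonical orientation.
#' @export
relationEdges <- function(x, relation) {
  if (is(x, "GraphView")) {
    stopIfNot(relation %in% x@relations, "relation not included in this view")
    x <- x@parent
  }
  x@edges[[relation]]
}

## ---- views --------------------------------------------------------------

#' DD / DGD view of a heterogeneous graph
#'
#' The `"DD"` view contains only the drug-disease bigraph; the `"DGD"` view
#' contains the drug-gene, disease-gene and gene-gene relations. The two
#' views partition the edge set.
#'
#' @param graph a [HeteroGraph-class].
#' @param which `"DD"` or `"DGD"`.
#' @return A [GraphView-class] sharing storage with `graph`.
#' @export
graphView <- function(graph, which = c("DD", "DGD")) {
  stopIfNot(is.character(which) && which[1L] %in% c("DD", "DGD"),
            sprintf("unknown view '%s' (use DD or DGD)", which[1L]))
  which <- which[1L]
  rels <- if (which == "DD") "drug-disease" else c("drug-gene", "disease-gene", "gene-gene")
  new("GraphView", parent = graph, relations = rels, label = which)
}

## ---- dataset manifests --------------------------------------------------

.MANIFEST_KEYS <- c("drug-disease" = "drug_disease", "drug-gene" = "drug_gene",
                    "disease-gene" = "disease_gene", "gene-gene" = "gene_gene")

#' Read a 4-file dataset manifest
#'
#' The manifest is YAML with keys `drug_disease`, `drug_gene`,
#' `disease_gene`, `gene_gene`, each naming an edge-list TSV (relative paths
#' resolved against the manifest's directory). All four files are loaded
#' into one [HeteroGraph-class].
#'
#' @param path manifest path.
#' @return A [HeteroGraph-class].
#' @export
readDatasetManifest <- function(path) {
  stopIfNot(file.exists(path), sprintf("manifest not found: %s", path),
            class = "geneDRIOError")
  man <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  registry <- nodeRegistry()
  edges <- list()
  for (rel in .RELATIONS) {
    f <- man[[.MANIFEST_KEYS[[rel]]]]
    stopIfNot(!is.null(f), sprintf("manifest missing key '%s'", .MANIFEST_KEYS[[rel]]),
              class = "geneDRIOError")
    if (!file.exists(f)) f <- file.path(base, f)
    stopIfNot(file.exists(f), sprintf("manifest file not found: %s", man[[.MANIFEST_KEYS[[rel]]]]),
              class = "geneDRIOError")
    got <- loadEdgeList(f, rel, registry)
    registry <- got$registry
    edges[[rel]] <- got$edges
  }
  buildHeteroGraph(registry, edges)
}

#' Write a HeteroGraph as 4 TSV edge lists plus a YAML manifest
#'
#' @param graph a [HeteroGraph-class].
#' @param dir output directory (created if needed).
#' @return Path of the manifest, invisibly.
#' @export
writeDataset <- function(graph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- setNames(paste0(gsub("-", "_", .RELATIONS), ".tsv"), .RELATIONS)
  for (rel in .RELATIONS) writeEdgeList(graph, rel, file.path(dir, files[[rel]]))
  man <- setNames(as.list(unname(files)), unname(.MANIFEST_KEYS[.RELATIONS]))
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"))
  invisible(file.path(dir, "manifest.yaml"))
}
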