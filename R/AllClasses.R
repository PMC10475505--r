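#' @import methods
#' @importFrom stats runif rnorm setNames
NULL

## Relation vocabulary. Endpoint types are fixed per relation; gene-gene is
## the only homogeneous relation and is stored min-id-first.
.RELATIONS <- c("drug-disease", "drug-gene", "disease-gene", "gene-gene")
.REL_TYPES <- list(
  "drug-disease" = c("drug", "disease"),
  "drug-gene"    = c("drug", "gene"),
  "disease-gene" = c("disease", "gene"),
  "gene-gene"    = c("gene", "gene")
)
.NODE_TYPES <- c("drug", "disease", "gene")

#' Relation names of the heterogeneous graph
#'
#' @return Character vector of the four relation names.
#' @export
relationNames <- function() .RELATIONS

#' NodeRegistry: typed node identity map
#'
#' Maps (type, name) pairs to dense integer ids. Ids are global across the
#' three node types and contiguous `1..N`, so id `i` is row `i` of every
#' embedding matrix.
#'
#' @slot name character vector; `name[i]` is the external name of node id `i`.
#' @slot type character vector; `type[i]` in `drug`, `disease`, `gene`.
#' @export
setClass("NodeRegistry",
  representation(name = "character", type = "character"))

setValidity("NodeRegistry", function(object) {
  if (length(object@name) != length(object@type))
    return("name and type must have equal length")
  if (anyDuplicated(object@name))
    return("node names must be unique across all types")
  if (length(object@type) && !all(object@type %in% .NODE_TYPES))
    return("node types must be drug, disease or gene")
  TRUE
})

#' Create an empty node registry
#'
#' @return A [NodeRegistry-class] with no nodes.
#' @export
nodeRegistry <- function() new("NodeRegistry", name = character(), type = character())

#' HeteroGraph: typed drug-gene-disease graph
#'
#' Holds the registry plus four undirected edge sets (drug-disease,
#' drug-gene, disease-gene, gene-gene) and per-relation adjacency lists.
#' Edges are stored once in canonical orientation (typed head first; min id
#' first for gene-gene), with no self-loops and no duplicates.
#'
#' @slot registry a [NodeRegistry-class].
#' @slot edges named list of 4 two-column integer matrices.
#' @slot adjacency named list of 4 per-node neighbor-id lists.
#' @export
setClass("HeteroGraph",
  representation(registry = "NodeRegistry", edges = "list", adjacency = "list"))

setValidity("HeteroGraph", function(object) {
  if (!identical(names(object@edges), .RELATIONS))
    return("edges must be a named list over the four relations")
  n <- length(object@registry@name)
  for (rel in .RELATIONS) {
    e <- object@edges[[rel]]
    if (!is.matrix(e) || ncol(e) != 2L) return(sprintf("edges[[%s]] must be a 2-column matrix", rel))
    if (nrow(e) == 0L) next
    if (any(e < 1L) || any(e > n)) return(sprintf("%s: endpoint id outside registry", rel))
    tt <- .REL_TYPES[[rel]]
    if (!all(object@registry@type[e[, 1L]] == tt[1L]) ||
        !all(object@registry@type[e[, 2L]] == tt[2L]))
      return(sprintf("%s: endpoint type mismatch", rel))
    if (any(e[, 1L] == e[, 2L])) return(sprintf("%s: self-loop stored", rel))
    if (anyDuplicated(paste(e[, 1L], e[, 2L]))) return(sprintf("%s: duplicate edge", rel))
  }
  TRUE
})

#' GraphView: a relation subset of a HeteroGraph
#'
#' The DD view exposes only drug-disease edges; the DGD view exposes
#' drug-gene, disease-gene and gene-gene edges. Storage is shared with the
#' parent graph.
#'
#' @slot parent the parent [HeteroGraph-class].
#' @slot relations character vector of included relation names.
#' @slot label `"DD"` or `"DGD"`.
#' @export
setClass("GraphView",
  representation(parent = "HeteroGraph", relations = "character", label = "character"))

#' GenePathSet: extracted gene paths keyed by anchor
#'
#' @slot paths named list: anchor id (as character) -> list of integer gene-id
#'   vectors. Every drug/disease anchor has an entry, possibly empty.
#' @slot LMax integer, maximum number of genes per path.
#' @slot KMax integer, maximum number of distinct paths per anchor.
#' @export
setClass("GenePathSet",
  representation(paths = "list", LMax = "integer", KMax = "integer"))

setValidity("GenePathSet", function(object) {
  if (object@LMax < 1L || object@KMax < 1L) return("LMax and KMax must be >= 1")
  for (p in object@paths) {
    if (length(p) > object@KMax) return("anchor exceeds KMax paths")
    if (length(p) && anyDuplicated(vapply(p, paste, "", collapse = ",")))
      return("duplicate path under an anchor")
  }
  TRUE
})

#' EmbeddingMatrix: per-node embedding rows tagged by pipeline stage
#'
#' @slot mat numeric matrix, one row per registry node.
#' @slot stage label: `"TransE"`, `"GMP"` or `"GCN"`.
#' @slot round non-negative integer round index (0 = initial).
#' @export
setClass("EmbeddingMatrix",
  representation(mat = "matrix", stage = "character", round = "integer"))

setValidity("EmbeddingMatrix", function(object) {
  if (!is.numeric(object@mat)) return("mat must be numeric")
  if (!all(is.finite(object@mat))) return("mat contains non-finite entries")
  if (!object@stage %in% c("TransE", "GMP", "GCN")) return("unknown stage label")
  if (object@round < 0L) return("round must be >= 0")
  TRUE
})

#' Construct an EmbeddingMatrix
#'
#' @param mat numeric matrix (rows = nodes).
#' @param stage stage label.
#' @param round round index.
#' @return An [EmbeddingMatrix-class].
#' @export
embeddingMatrix <- function(mat, stage = "TransE", round = 0L) {
  new("EmbeddingMatrix", mat = mat, stage = stage, round = as.integer(round))
}

#' @describeIn embeddingMatrix extract the plain numeric matrix.
#' @param x an `EmbeddingMatrix`.
#' @export
embMatrix <- function(x) if (is(x, "EmbeddingMatrix")) x@mat else x

#' @describeIn embeddingMatrix stage label accessor.
#' @export
embStage <- function(x) x@stage

#' TransEState: entity/relation embeddings of the translation model
#'
#' @slot entity numeric `|V| x d` matrix, rows L2-normalized.
#' @slot relation numeric `3 x d` matrix (drug-gene, disease-gene, gene-gene).
#' @slot margin positive ranking margin.
#' @slot normOrder 1 or 2, the norm of the score.
#' @slot loss numeric vector of per-epoch mean losses.
#' @export
setClass("TransEState",
  representation(entity = "matrix", relation = "matrix", margin = "numeric",
                 normOrder = "integer", loss = "numeric"))

setValidity("TransEState", function(object) {
  if (!object@normOrder %in% c(1L, 2L)) return("normOrder must be 1 or 2")
  if (object@margin <= 0) return("margin must be positive")
  if (nrow(object@relation) != 3L) return("relation matrix must have 3 rows")
  TRUE
})

#' GeneDRModel: trained link-prediction model
#'
#' @slot params nested list of weights (gene-path encoder per round,
#'   GCN layers per round, predictor head).
#' @slot variant `"full"`, `"no_gmp"` or `"no_lstm"`.
#' @slot config the training configuration snapshot (list).
#' @slot lossLog numeric per-epoch training loss.
#' @export
setClass("GeneDRModel",
  representation(params = "list", variant = "character", config = "list",
                 lossLog = "numeric"))

setValidity("GeneDRModel", function(object) {
  if (!object@variant %in% c("full", "no_gmp", "no_lstm")) return("unknown variant")
  if (object@variant == "no_gmp" && !is.null(object@params$gmp))
    return("no_gmp variant must not carry gene-path parameters")
  TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "NodeRegistry", function(object) {
  cnt <- table(factor(object@type, levels = .NODE_TYPES))
  cat(sprintf("NodeRegistry with %d nodes (%d drugs, %d diseases, %d genes)\n",
              length(object@name), cnt[["drug"]], cnt[["disease"]], cnt[["gene"]]))
})

setMethod("show", "HeteroGraph", function(object) {
  show(object@registry)
  for (rel in .RELATIONS)
    cat(sprintf("  %-12s %6d edges\n", rel, nrow(object@edges[[rel]])))
})

setMethod("show", "GraphView", function(object) {
  cat(sprintf("GraphView '%s' (%s): %d edges\n", object@label,
              paste(object@relations, collapse = ", "),
              sum(vapply(object@parent@edges[object@relations], nrow, 0L))))
})

setMethod("show", "GenePathSet", function(object) {
  np <- vapply(object@paths, length, 0L)
  cat(sprintf("GenePathSet: %d anchors, %d paths (LMax=%d, KMax=%d), %d anchors without paths\n",
              length(np), sum(np), object@LMax, object@KMax, sum(np == 0L)))
})

setMethod("show", "EmbeddingMatrix", function(object) {
  cat(sprintf("EmbeddingMatrix %d x %d, stage %s, round %d\n",
              nrow(object@mat), ncol(object@mat), object@stage, object@round))
})

setMethod("show", "TransEState", function(object) {
  cat(sprintf("TransEState: %d entities, d=%d, L%d norm, margin %.2f, %d epochs (final loss %.4f)\n",
              nrow(object@entity), ncol(object@entity), object@normOrder,
              object@margin, length(object@loss),
              if (length(object@loss)) object@loss[length(object@loss)] else NA_real_))
})

setMethod("show", "GeneDRModel", function(object) {
  cat(sprintf("GeneDRModel variant '%s', d=%d, %d GCN layers, %d rounds, %d epochs trained\n",
              object@variant, object@config$hidden, object@config$gcn_layers,
              object@config$rounds, length(object@lossLog)))
})
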