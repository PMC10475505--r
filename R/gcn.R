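#' @include AllClasses.R nn.R
#' @importFrom Matrix sparseMatrix Diagonal
NULL

#' Normalized adjacency with self-loops
#'
#' Builds `D^(-1/2) (A + I) D^(-1/2)` (`sym`) or `D^(-1) (A + I)` (`row`)
#' as a sparse matrix over all `n` nodes. For cross-validation, pass the
#' training-fold edges only so held-out associations never enter the
#' operator.
#'
#' @param x a [GraphView-class] (all its relations' edges are used) or a
#'   2-column integer edge matrix.
#' @param n node count (taken from the view if omitted).
#' @param mode `"sym"` or `"row"`.
#' @return A sparse `dgCMatrix`.
#' @export
normalizeAdjacency <- function(x, n = NULL, mode = c("sym", "row")) {
  mode <- match.arg(mode)
  if (is(x, "GraphView")) {
    if (is.null(n)) n <- nodeCount(x)
    e <- do.call(rbind, lapply(x@relations, function(r) relationEdges(x, r)))
  } else {
    e <- x
    stopIfNot(!is.null(n), "node count n required with a raw edge matrix",
              class = "geneDRConfigError")
  }
  stopIfNot(n >= 1L, "empty node set", class = "geneDRConfigError")
  A <- Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]), j = c(e[, 2L], e[, 1L]),
                            x = 1, dims = c(n, n)) + Matrix::Diagonal(n)
  A@x[] <- pmin(A@x, 1)  # guard against accidental duplicates
  deg <- Matrix::rowSums(A)
  if (mode == "sym") {
    Dinv <- Matrix::Diagonal(n, 1 / sqrt(deg))
    methods::as(Dinv %*% A %*% Dinv, "CsparseMatrix")
  } else {
    methods::as(Matrix::Diagonal(n, 1 / deg) %*% A, "CsparseMatrix")
  }
}

#' Initialize GCN layer parameters
#'
#' @param d width (all layers `d x d`).
#' @param L number of layers (>= 1).
#' @param seed RNG seed.
#' @param activation inter-layer activation, `"relu"` (default),
#'   `"identity"`; the last layer is always linear so the embeddings feed
#'   the predictor.
#' @return Parameter list with `W`, `b` lists and the activation name.
#' @export
gcnParams <- function(d, L = 3L, seed = 1L, activation = "relu") {
  stopIfNot(L >= 1L, "at least one GCN layer required", class = "geneDRConfigError")
  withSeed(seed, {
    list(W = lapply(seq_len(L), function(l) initW(d, d)),
         b = lapply(seq_len(L), function(l) numeric(d)),
         activation = activation)
  })
}

.gcnAct <- function(x, name) if (identical(name, "relu")) relu(x) else x

## forward with optional cache; Ahat sparse, H dense (n x d)
gcnForwardCore <- function(params, Ahat, H, want_cache = FALSE) {
  L <- length(params$W)
  Zs <- vector("list", L + 1L)
  Ss <- vector("list", L)
  Zs[[1L]] <- H
  for (l in seq_len(L)) {
    AZ <- as.matrix(Ahat %*% Zs[[l]])
    S <- AZ %*% params$W[[l]] + rep(params$b[[l]], each = nrow(H))
    Ss[[l]] <- S
    Zs[[l + 1L]] <- if (l < L) .gcnAct(S, params$activation) else S
  }
  res <- list(H = Zs[[L + 1L]])
  if (want_cache) res$cache <- list(Zs = Zs, Ss = Ss, Ahat = Ahat)
  res
}

gcnBackwardCore <- function(params, cache, dHout) {
  L <- length(params$W)
  Ahat <- cache$Ahat
  dW <- vector("list", L); db <- vector("list", L)
  dZ <- dHout
  for (l in rev(seq_len(L))) {
    dS <- if (l < L && identical(params$activation, "relu")) dZ * (cache$Ss[[l]] > 0) else dZ
    AZ <- as.matrix(Ahat %*% cache$Zs[[l]])
    dW[[l]] <- crossprod(AZ, dS)
    db[[l]] <- colSums(dS)
    dZ <- as.matrix(Matrix::t(Ahat) %*% (dS %*% t(params$W[[l]])))
  }
  list(grads = list(W = dW, b = db), dH = dZ)
}

#' GCN forward pass
#'
#' `H^(l) = act(A_hat H^(l-1) W^(l) + b^(l))` for `l = 1..L`, with no
#' activation after the last layer.
#'
#' @param params from [gcnParams()].
#' @param Ahat normalized adjacency from [normalizeAdjacency()].
#' @param H an [EmbeddingMatrix-class] or plain matrix.
#' @return An [EmbeddingMatrix-class] with stage `"GCN"`.
#' @export
gcnForward <- function(params, Ahat, H) {
  round_in <- if (is(H, "EmbeddingMatrix")) H@round else 0L
  M <- embMatrix(H)
  stopIfNot(all(is.finite(M)), "embedding matrix contains non-finite rows",
            class = "geneDRValidationError")
  stopIfNot(ncol(M) == nrow(params$W[[1L]]), "embedding width does not match GCN width",
            class = "geneDRConfigError")
  out <- gcnForwardCore(params, Ahat, M)
  embeddingMatrix(out$H, stage = "GCN", round = round_in)
}
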