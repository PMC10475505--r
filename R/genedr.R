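#' @include AllClasses.R nn.R gmp.R gcn.R transe.R paths.R
NULL

#' Training configuration
#'
#' Defaults follow the method's reference settings: hidden size 128 for the
#' LSTM and GCN, 3 GCN layers, learning rate 0.001, gene paths of at most 4
#' genes and at most 100 distinct paths per node, and two alternation
#' rounds of gene-path then bigraph message passing. The loss is binary
#' cross-entropy under Adam; early stopping watches validation AUPR.
#'
#' @param hidden embedding / hidden dimension `d`.
#' @param gcn_layers GCN depth.
#' @param lr learning rate.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience on validation AUPR (`Inf`
#'   disables early stopping).
#' @param val_fraction fraction of training samples held out for early
#'   stopping (0 disables).
#' @param L_max,K_max,n_tries gene-path extraction limits.
#' @param rounds alternation rounds (>= 1).
#' @param variant `"full"`, `"no_gmp"` or `"no_lstm"`.
#' @param share_gmp_weights reuse one encoder across rounds.
#' @param predictor_hidden hidden layer in the scoring head.
#' @param threshold decision threshold for F1/Recall.
#' @param k_folds folds of the cross-validation protocol.
#' @param transe_epochs,transe_lr,transe_margin,transe_norm TransE settings.
#' @param seed RNG seed governing every random stage.
#' @return Config list of class `genedrConfig`.
#' @export
genedrConfig <- function(hidden = 128L, gcn_layers = 3L, lr = 0.001,
                         epochs = 1000L, patience = 50L, val_fraction = 0.1,
                         L_max = 4L, K_max = 100L, n_tries = 10L * K_max,
                         rounds = 2L, variant = c("full", "no_gmp", "no_lstm"),
                         share_gmp_weights = FALSE, predictor_hidden = TRUE,
                         threshold = 0.5, k_folds = 5L,
                         transe_epochs = 500L, transe_lr = 0.01,
                         transe_margin = 1, transe_norm = 2L, seed = 1L) {
  variant <- match.arg(variant)
  cfg <- list(hidden = as.integer(hidden), gcn_layers = as.integer(gcn_layers),
              lr = lr, epochs = as.integer(epochs), patience = patience,
              val_fraction = val_fraction, L_max = as.integer(L_max),
              K_max = as.integer(K_max), n_tries = as.integer(n_tries),
              rounds = as.integer(rounds), variant = variant,
              share_gmp_weights = isTRUE(share_gmp_weights),
              predictor_hidden = isTRUE(predictor_hidden),
              threshold = threshold, k_folds = as.integer(k_folds),
              transe_epochs = as.integer(transe_epochs), transe_lr = transe_lr,
              transe_margin = transe_margin, transe_norm = as.integer(transe_norm),
              seed = as.integer(seed))
  stopIfNot(cfg$rounds >= 1L && cfg$hidden >= 1L && cfg$gcn_layers >= 1L &&
            cfg$epochs >= 0L && cfg$lr > 0,
            "config values must be positive (rounds >= 1)", class = "geneDRConfigError")
  class(cfg) <- c("genedrConfig", "list")
  cfg
}

#' Read a configuration from YAML
#'
#' Top-level keys mirror the arguments of [genedrConfig()].
#'
#' @param path YAML file.
#' @param ... overrides applied after the file.
#' @return A `genedrConfig`.
#' @export
readConfig <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  vals <- utils::modifyList(vals, list(...))
  do.call(genedrConfig, vals)
}

#' Build an untrained model of a given variant
#'
#' `full` is the two-strategy architecture (LSTM gene-path message passing
#' alternated with bigraph GCN); `no_lstm` swaps the LSTM for a single
#' chain-GCN path encoder; `no_gmp` drops gene paths entirely and runs one
#' heterogeneous GCN over the combined drug-disease + gene relations.
#'
#' @param config a [genedrConfig()].
#' @return A [GeneDRModel-class] with seeded, untrained weights.
#' @export
buildVariant <- function(config) {
  stopIfNot(inherits(config, "genedrConfig"), "config must come from genedrConfig()",
            class = "geneDRConfigError")
  d <- config$hidden
  withSeed(config$seed, {
    params <- list()
    if (config$variant != "no_gmp") {
      encoder <- if (config$variant == "no_lstm") "pgcn" else "lstm"
      nsets <- if (config$share_gmp_weights) 1L else config$rounds
      params$gmp <- lapply(seq_len(nsets), function(r)
        gmpParams(d, encoder = encoder, seed = sample.int(.Machine$integer.max, 1L)))
      params$gcn <- lapply(seq_len(config$rounds), function(r)
        gcnParams(d, L = config$gcn_layers, seed = sample.int(.Machine$integer.max, 1L)))
    } else {
      params$gcn <- list(gcnParams(d, L = config$gcn_layers,
                                   seed = sample.int(.Machine$integer.max, 1L)))
    }
    params$pred <- predInit(d, hidden = config$predictor_hidden)
    new("GeneDRModel", params = params, variant = config$variant,
        config = unclass(config), lossLog = numeric(0))
  })
}

## round-index into the gmp parameter list (shared weights use one set)
.gmpAt <- function(model, r) {
  if (isTRUE(model@config$share_gmp_weights)) model@params$gmp[[1L]]
  else model@params$gmp[[r]]
}

#' Forward pass: drug-disease link scores
#'
#' For the full / no_lstm variants, runs `rounds` alternations of gene-path
#' message passing (update of drug/disease rows from attention-pooled path
#' encodings) followed by GCN on the drug-disease bigraph; gene rows
#' re-enter each round at their initial (TransE) values. Final drug and
#' disease embeddings are concatenated into the fully connected scoring
#' head. For `no_gmp`, a single heterogeneous GCN over the combined
#' adjacency replaces the alternation.
#'
#' @param model a [GeneDRModel-class].
#' @param graph the [HeteroGraph-class].
#' @param Ahat normalized adjacency of the DD bigraph (or of the combined
#'   graph for `no_gmp`), built from training edges only.
#' @param pathSet a [GenePathSet-class] (ignored by `no_gmp`).
#' @param Htranse initial [EmbeddingMatrix-class].
#' @param pairs 2-column matrix of (drug id, disease id).
#' @param want_cache keep intermediate states for backprop (internal).
#' @return Numeric scores in (0,1); attribute `calls` counts the gene-path
#'   and GCN invocations of this forward pass.
#' @export
genedrForward <- function(model, graph, Ahat, pathSet, Htranse, pairs,
                          want_cache = FALSE) {
  H0 <- embMatrix(Htranse)
  stopIfNot(nrow(H0) == nodeCount(graph), "embedding does not cover the registry",
            class = "geneDRValidationError")
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  stopIfNot(all(nodeType(graph, pairs[, 1L]) == "drug") &&
            all(nodeType(graph, pairs[, 2L]) == "disease"),
            "pairs must be (drug, disease)", class = "geneDRTypeConflict")
  calls <- c(gmp = 0L, gcn = 0L)
  caches <- list()
  if (model@variant == "no_gmp") {
    fw <- gcnForwardCore(model@params$gcn[[1L]], Ahat, H0, want_cache = want_cache)
    calls["gcn"] <- 1L
    H <- fw$H
    caches$gcn <- list(fw$cache)
  } else {
    anchors <- c(nodesOfType(graph, "drug"), nodesOfType(graph, "disease"))
    genes <- nodesOfType(graph, "gene")
    H <- H0
    caches$gmp <- caches$gcn <- vector("list", model@config$rounds)
    for (r in seq_len(model@config$rounds)) {
      g1 <- gmpForwardCore(.gmpAt(model, r), pathSet, H, anchors, want_cache = want_cache)
      calls["gmp"] <- calls["gmp"] + 1L
      g2 <- gcnForwardCore(model@params$gcn[[r]], Ahat, g1$H, want_cache = want_cache)
      calls["gcn"] <- calls["gcn"] + 1L
      H <- g2$H
      H[genes, ] <- H0[genes, , drop = FALSE]  # genes re-enter at TransE values
      caches$gmp[[r]] <- g1$cache
      caches$gcn[[r]] <- g2$cache
    }
  }
  pf <- predForward(model@params$pred, H, pairs)
  scores <- pf$p
  attr(scores, "calls") <- calls
  if (want_cache)
    return(list(scores = scores, pred_cache = pf$cache, caches = caches,
                n = nrow(H0), genes = if (model@variant == "no_gmp") integer()
                                      else nodesOfType(graph, "gene")))
  scores
}

## Full backward pass; labels y in {0,1}; BCE mean loss. Returns grads tree
## mirroring model@params plus the loss value.
genedrBackward <- function(model, fwd, y) {
  p <- as.numeric(fwd$scores)
  B <- length(y)
  eps <- 1e-12
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  dz <- (p - y) / B
  pb <- predBackward(model@params$pred, fwd$pred_cache, dz, fwd$n)
  grads <- list(pred = pb$grads)
  dH <- pb$dH
  if (model@variant == "no_gmp") {
    gb <- gcnBackwardCore(model@params$gcn[[1L]], fwd$caches$gcn[[1L]], dH)
    grads$gcn <- list(gb$grads)
  } else {
    rounds <- model@config$rounds
    grads$gcn <- vector("list", rounds)
    gmp_sets <- if (isTRUE(model@config$share_gmp_weights)) 1L else rounds
    grads$gmp <- vector("list", gmp_sets)
    for (r in rev(seq_len(rounds))) {
      dH[fwd$genes, ] <- 0  # gene rows were reset to constants after the GCN
      gb <- gcnBackwardCore(model@params$gcn[[r]], fwd$caches$gcn[[r]], dH)
      grads$gcn[[r]] <- gb$grads
      mb <- gmpBackwardCore(.gmpAt(model, r), fwd$caches$gmp[[r]], gb$dH)
      slot_r <- if (isTRUE(model@config$share_gmp_weights)) 1L else r
      grads$gmp[[slot_r]] <- if (is.null(grads$gmp[[slot_r]])) mb$grads
                             else mapParams(`+`, grads$gmp[[slot_r]], mb$grads)
      dH <- mb$dH
    }
    ## order grads like params (gmp, gcn, pred irrelevant: matched by name)
  }
  list(grads = grads, loss = loss)
}

#' Train a model on one fold's link samples
#'
#' Minimizes binary cross-entropy of the link scores against the labels
#' with Adam. The bigraph adjacency is built from the positive training
#' samples only, so held-out associations never enter message passing.
#' Optionally holds out a validation fraction for early stopping on AUPR.
#' Deterministic given `config$seed`.
#'
#' @param graph the [HeteroGraph-class].
#' @param samples data.frame with integer columns `drug`, `disease` and
#'   binary `label` (the training split of one fold).
#' @param config a [genedrConfig()].
#' @param Htranse optional precomputed initial embeddings (computed from
#'   the DGD view when omitted).
#' @param pathSet optional precomputed [GenePathSet-class].
#' @return A [GeneDRModel-class] carrying the best weights and loss log.
#' @export
trainGeneDR <- function(graph, samples, config, Htranse = NULL, pathSet = NULL) {
  stopIfNot(nrow(samples) > 0L, "empty training set", class = "geneDRTrainingError")
  stopIfNot(length(unique(samples$label)) == 2L,
            "training set must contain both classes", class = "geneDRTrainingError")
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

  ## adjacency from training positives (plus all DGD relations for no_gmp)
  pos <- as.matrix(samples[samples$label == 1L, c("drug", "disease")])
  Ahat <- if (config$variant == "no_gmp") {
    e <- rbind(pos, relationEdges(graph, "drug-gene"),
               relationEdges(graph, "disease-gene"), relationEdges(graph, "gene-gene"))
    normalizeAdjacency(e, n = nodeCount(graph))
  } else normalizeAdjacency(pos, n = nodeCount(graph))

  model <- buildVariant(config)
  withSeed(config$seed + 1L, {
    ## validation split for early stopping
    idx <- seq_len(nrow(samples))
    use_val <- config$val_fraction > 0 && is.finite(config$patience)
    if (use_val) {
      nv <- max(2L, floor(config$val_fraction * nrow(samples)))
      vidx <- sample(idx, nv)
      if (length(unique(samples$label[vidx])) < 2L) use_val <- FALSE
    }
    tidx <- if (use_val) setdiff(idx, vidx) else idx
    if (length(unique(samples$label[tidx])) < 2L) { tidx <- idx; use_val <- FALSE }
    tr_pairs <- as.matrix(samples[tidx, c("drug", "disease")])
    tr_y <- samples$label[tidx]
    if (use_val) {
      va_pairs <- as.matrix(samples[vidx, c("drug", "disease")])
      va_y <- samples$label[vidx]
    }

    opt <- adamInit(model@params)
    best <- list(params = model@params, score = -Inf, epoch = 0L)
    losses <- numeric(0)
    wait <- 0L
    for (ep in seq_len(config$epochs)) {
      fwd <- genedrForward(model, graph, Ahat, pathSet, Htranse, tr_pairs,
                           want_cache = TRUE)
      bw <- genedrBackward(model, fwd, tr_y)
      losses <- c(losses, bw$loss)
      st <- adamStep(model@params, bw$grads, opt, lr = config$lr)
      model@params <- st$params
      opt <- st$state
      if (use_val) {
        vs <- genedrForward(model, graph, Ahat, pathSet, Htranse, va_pairs)
        vm <- computeMetrics(as.numeric(vs), va_y, threshold = config$threshold)
        if (vm$aupr > best$score + 1e-9) {
          best <- list(params = model@params, score = vm$aupr, epoch = ep)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= config$patience) break
        }
      } else if (bw$loss < -best$score) {
        best <- list(params = model@params, score = -bw$loss, epoch = ep)
      }
    }
    if (best$epoch > 0L) model@params <- best$params
    model@lossLog <- losses
    model
  })
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the weights, the config snapshot and the node
#' registry (names and types) so that a model is only ever applied to the
#' graph it was trained on.
#'
#' @param model a trained [GeneDRModel-class].
#' @param graph the training [HeteroGraph-class].
#' @param path checkpoint file (RDS).
#' @return `path` invisibly (save); the [GeneDRModel-class] (load).
#' @export
saveModel <- function(model, graph, path) {
  saveRDS(list(model = model,
               registry = list(name = graph@registry@name,
                               type = graph@registry@type)),
          path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path, graph) {
  obj <- readRDS(path)
  stopIfNot(identical(obj$registry$name, graph@registry@name) &&
            identical(obj$registry$type, graph@registry@type),
            "checkpoint registry does not match this graph",
            class = "geneDRValidationError")
  obj$model
}

#' Score drug-disease pairs with a trained model
#'
#' @param model trained [GeneDRModel-class].
#' @param graph the graph used in training.
#' @param Ahat the training adjacency (see [trainGeneDR()]).
#' @param pathSet the path set used in training (`NULL` for `no_gmp`).
#' @param Htranse the initial embeddings used in training.
#' @param pairs 2-column matrix of (drug, disease) ids.
#' @return Numeric score vector in (0,1).
#' @export
predictPairs <- function(model, graph, Ahat, pathSet, Htranse, pairs) {
  as.numeric(genedrForward(model, graph, Ahat, pathSet, Htranse, pairs))
}
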