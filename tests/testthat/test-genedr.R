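# Shared small forward-pass context on the study fixture.
fwdContext <- function(d = 4L) {
  memo(paste0("fwdctx", d), {
    sim <- studyFixture()
    g <- sim$graph
    dgd <- graphView(g, "DGD")
    ps <- extractGenePaths(dgd, K_max = 5L, n_tries = 30L, seed = 7L)
    Ht <- embeddingMatrix(withr::with_seed(3, matrix(rnorm(nodeCount(g) * d), nodeCount(g), d)))
    pos <- relationEdges(g, "drug-disease")
    list(g = g, ps = ps, Ht = Ht,
         Add = normalizeAdjacency(pos, n = nodeCount(g)),
         Ahet = normalizeAdjacency(rbind(pos, relationEdges(g, "drug-gene"),
                                         relationEdges(g, "disease-gene"),
                                         relationEdges(g, "gene-gene")),
                                   n = nodeCount(g)),
         pairs = cbind(nodesOfType(g, "drug")[1:6], nodesOfType(g, "disease")[1:6]))
  })
}

test_that("zeroed predictor scores 0.5 and pair order does not matter", {
  ctx <- fwdContext()
  cfg <- genedrConfig(hidden = 4L, gcn_layers = 2L, seed = 2L)
  model <- buildVariant(cfg)
  model@params$pred$W1[] <- 0; model@params$pred$b1[] <- 0
  model@params$pred$w2[] <- 0; model@params$pred$b2 <- 0
  sc <- genedrForward(model, ctx$g, ctx$Add, ctx$ps, ctx$Ht, ctx$pairs)
  expect_equal(as.numeric(sc), rep(0.5, nrow(ctx$pairs)))

  model2 <- buildVariant(cfg)
  s1 <- as.numeric(genedrForward(model2, ctx$g, ctx$Add, ctx$ps, ctx$Ht, ctx$pairs))
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  s2 <- as.numeric(genedrForward(model2, ctx$g, ctx$Add, ctx$ps, ctx$Ht,
                                 ctx$pairs[perm, ]))
  expect_equal(s2, s1[perm], tolerance = 1e-6)
  ## wrong node types rejected
  expect_error(genedrForward(model2, ctx$g, ctx$Add, ctx$ps, ctx$Ht,
                             ctx$pairs[, c(2L, 1L)]),
               class = "geneDRTypeConflict")
})

test_that("two rounds invoke the two strategies exactly twice each", {
  ctx <- fwdContext()
  cfg <- genedrConfig(hidden = 4L, gcn_layers = 2L, rounds = 2L, seed = 5L)
  sc <- genedrForward(buildVariant(cfg), ctx$g, ctx$Add, ctx$ps, ctx$Ht, ctx$pairs)
  expect_identical(attr(sc, "calls"), c(gmp = 2L, gcn = 2L))
  cfg1 <- genedrConfig(hidden = 4L, gcn_layers = 2L, rounds = 1L, seed = 5L)
  sc1 <- genedrForward(buildVariant(cfg1), ctx$g, ctx$Add, ctx$ps, ctx$Ht, ctx$pairs)
  expect_identical(attr(sc1, "calls"), c(gmp = 1L, gcn = 1L))
})

test_that("no_gmp forward is identical to a direct heterogeneous GCN call", {
  ctx <- fwdContext()
  cfg <- genedrConfig(hidden = 4L, gcn_layers = 3L, variant = "no_gmp", seed = 8L)
  model <- buildVariant(cfg)
  sc <- as.numeric(genedrForward(model, ctx$g, ctx$Ahet, NULL, ctx$Ht, ctx$pairs))
  Hg <- embMatrix(gcnForward(model@params$gcn[[1L]], ctx$Ahet, ctx$Ht))
  X <- cbind(Hg[ctx$pairs[, 1L], ], Hg[ctx$pairs[, 2L], ])
  p <- model@params$pred
  direct <- drop(1 / (1 + exp(-(pmax(X %*% p$W1 + rep(p$b1, each = 6L), 0) %*% p$w2 + p$b2))))
  expect_identical(sc, direct)
})

test_that("full forward equals the hand composition of the module ops", {
  ctx <- fwdContext()
  cfg <- genedrConfig(hidden = 4L, gcn_layers = 2L, rounds = 2L, seed = 11L)
  model <- buildVariant(cfg)
  sc <- as.numeric(genedrForward(model, ctx$g, ctx$Add, ctx$ps, ctx$Ht, ctx$pairs))
  ## independent recomposition through the public single-op API
  g <- ctx$g
  genes <- nodesOfType(g, "gene")
  H0 <- embMatrix(ctx$Ht)
  H <- H0
  for (r in 1:2) {
    H <- embMatrix(gmpUpdate(model@params$gmp[[r]], ctx$ps, H, g))
    H <- embMatrix(gcnForward(model@params$gcn[[r]], ctx$Add, H))
    H[genes, ] <- H0[genes, ]
  }
  X <- cbind(H[ctx$pairs[, 1L], ], H[ctx$pairs[, 2L], ])
  p <- model@params$pred
  byHand <- drop(1 / (1 + exp(-(pmax(X %*% p$W1 + rep(p$b1, each = 6L), 0) %*% p$w2 + p$b2))))
  expect_equal(sc, byHand, tolerance = 1e-10)
})

test_that("no_lstm path encoding is the mean of chain-GCN-transformed nodes", {
  ctx <- fwdContext()
  d <- 4L
  par <- gmpParams(d, encoder = "pgcn", seed = 3L)
  H <- embMatrix(ctx$Ht)
  ## 1-gene path: 2-node chain, Ahat = 1/2 everywhere; hand evaluation
  anchor <- nodesOfType(ctx$g, "drug")[1L]
  gene <- neighborsOf(ctx$g, anchor, "drug-gene")[1L]
  skip_if(is.na(gene))
  X <- rbind(H[gene, ], H[anchor, ])
  pre <- (0.5 * (X[1, ] + X[2, ])) # both rows of Ahat %*% X are the mean
  hand <- tanh(rbind(pre, pre) %*% par$enc$Wp + rep(par$enc$bp, each = 2L))
  expect_equal(encodePath(par, anchor, gene, H), colMeans(hand), tolerance = 1e-10)
})

test_that("variant gradients agree with numeric differentiation end to end", {
  sim <- generateSynthetic(synthConfig(n_drugs = 4L, n_diseases = 4L, n_genes = 9L,
                                       n_modules = 3L, genes_per_module = 3L,
                                       p_intra = 0.9, p_inter = 0.1, k_anchor = 2L,
                                       noise_rate = 0, seed = 3L))
  g <- sim$graph
  d <- 3L
  dgd <- graphView(g, "DGD")
  Ht <- embeddingMatrix(withr::with_seed(2, matrix(rnorm(nodeCount(g) * d, sd = 0.5),
                                                   nodeCount(g), d)))
  ps <- extractGenePaths(dgd, L_max = 3L, K_max = 4L, n_tries = 40L, seed = 2L)
  pos <- relationEdges(g, "drug-disease")
  pairs <- cbind(c(1L, 2L, 3L), c(5L, 6L, 7L))
  y <- c(1, 0, 1)
  for (variant in c("full", "no_lstm", "no_gmp")) {
    cfg <- genedrConfig(hidden = d, gcn_layers = 2L, variant = variant, seed = 5L)
    model <- buildVariant(cfg)
    Ahat <- if (variant == "no_gmp")
      normalizeAdjacency(rbind(pos, relationEdges(g, "drug-gene"),
                               relationEdges(g, "disease-gene"),
                               relationEdges(g, "gene-gene")), n = nodeCount(g))
    else normalizeAdjacency(pos, n = nodeCount(g))
    fwd <- genedrForward(model, g, Ahat, ps, Ht, pairs, want_cache = TRUE)
    bw <- geneDR:::genedrBackward(model, fwd, y)
    lossLeaf <- function(mod) {
      p <- as.numeric(genedrForward(mod, g, Ahat, ps, Ht, pairs))
      -mean(y * log(p + 1e-12) + (1 - y) * log(1 - p + 1e-12))
    }
    ## one representative leaf per block
    leafs <- if (variant == "no_gmp") {
      list(list(get = function(m) m@params$gcn[[1L]]$W[[1L]][, 1L],
                set = function(m, v) { m@params$gcn[[1L]]$W[[1L]][, 1L] <- v; m },
                gr = bw$grads$gcn[[1L]]$W[[1L]][, 1L]))
    } else {
      encnm <- if (variant == "no_lstm") "Wp" else "Wx"
      list(
        list(get = function(m) m@params$gmp[[1L]]$enc[[encnm]][1L, ],
             set = function(m, v) { m@params$gmp[[1L]]$enc[[encnm]][1L, ] <- v; m },
             gr = bw$grads$gmp[[1L]]$enc[[encnm]][1L, ]),
        list(get = function(m) m@params$gmp[[2L]]$w_att,
             set = function(m, v) { m@params$gmp[[2L]]$w_att <- v; m },
             gr = bw$grads$gmp[[2L]]$w_att),
        list(get = function(m) m@params$gcn[[2L]]$W[[1L]][, 1L],
             set = function(m, v) { m@params$gcn[[2L]]$W[[1L]][, 1L] <- v; m },
             gr = bw$grads$gcn[[2L]]$W[[1L]][, 1L]))
    }
    leafs <- c(leafs, list(
      list(get = function(m) m@params$pred$w2[, 1L],
           set = function(m, v) { m@params$pred$w2[, 1L] <- v; m },
           gr = bw$grads$pred$w2[, 1L])))
    for (lf in leafs) {
      num <- numGrad(function(v) lossLeaf(lf$set(model, v)), lf$get(model), eps = 1e-5)
      expect_equal(lf$gr, num, tolerance = 1e-4)
    }
  }
})

test_that("training memorizes a tiny problem, starts at ln 2, and is reproducible", {
  sim <- generateSynthetic(synthConfig(n_drugs = 4L, n_diseases = 4L, n_genes = 9L,
                                       n_modules = 3L, genes_per_module = 3L,
                                       p_intra = 0.9, p_inter = 0.1, k_anchor = 2L,
                                       noise_rate = 0, seed = 3L))
  g <- sim$graph
  cfg <- genedrConfig(hidden = 8L, gcn_layers = 2L, epochs = 200L, lr = 0.01,
                      patience = Inf, val_fraction = 0, K_max = 5L, n_tries = 30L,
                      transe_epochs = 30L, seed = 4L)
  dd <- relationEdges(g, "drug-disease")
  pospair <- dd[1L, ]
  negpair <- NULL
  for (r in nodesOfType(g, "drug")) for (z in nodesOfType(g, "disease"))
    if (is.null(negpair) && !any(dd[, 1L] == r & dd[, 2L] == z)) negpair <- c(r, z)
  samples <- data.frame(drug = c(pospair[1L], negpair[1L]),
                        disease = c(pospair[2L], negpair[2L]), label = c(1L, 0L))
  m <- trainGeneDR(g, samples, cfg)
  expect_lt(min(m@lossLog), 0.2)            # memorization sanity
  ## near-zero initial logits: first-epoch loss sits at ln 2 per sample
  expect_equal(m@lossLog[1L], log(2), tolerance = 0.1)
  ## determinism
  m2 <- trainGeneDR(g, samples, cfg)
  expect_identical(m@lossLog, m2@lossLog)
  ## single-class training set rejected
  expect_error(trainGeneDR(g, samples[1L, ], cfg), class = "geneDRTrainingError")
})

test_that("checkpoints round-trip and refuse a mismatched registry", {
  ctx <- fwdContext()
  cfg <- genedrConfig(hidden = 4L, gcn_layers = 2L, seed = 13L)
  model <- buildVariant(cfg)
  f <- withr::local_tempfile(fileext = ".ckpt")
  saveModel(model, ctx$g, f)
  back <- loadModel(f, ctx$g)
  expect_identical(back@params, model@params)
  s1 <- as.numeric(genedrForward(model, ctx$g, ctx$Add, ctx$ps, ctx$Ht, ctx$pairs))
  s2 <- as.numeric(genedrForward(back, ctx$g, ctx$Add, ctx$ps, ctx$Ht, ctx$pairs))
  expect_identical(s1, s2)
  expect_error(loadModel(f, chainGraph()), class = "geneDRValidationError")
})

test_that("all variants run end to end on the fixture and emit the four metrics", {
  g <- studyFixture()$graph
  for (variant in c("full", "no_gmp", "no_lstm")) {
    cfg <- genedrConfig(hidden = 8L, gcn_layers = 2L, epochs = 5L, variant = variant,
                        patience = Inf, val_fraction = 0, K_max = 5L, n_tries = 25L,
                        transe_epochs = 20L, seed = 6L)
    cv <- crossValidate(g, cfg, folds = 0L)
    expect_named(cv$mean, c("aupr", "auc", "f1", "recall"))
    expect_true(all(cv$per_fold[, c("aupr", "auc", "f1", "recall")] >= 0 &
                    cv$per_fold[, c("aupr", "auc", "f1", "recall")] <= 1))
  }
})
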