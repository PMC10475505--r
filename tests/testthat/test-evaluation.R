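test_that("fold construction is balanced 1:1, disjoint and leak-free", {
  g <- studyFixture()$graph
  samples <- makeFolds(g, k = 5L, seed = 3L)
  pos <- relationEdges(g, "drug-disease")
  keyOf <- function(d, z) paste(d, z, sep = ":")
  posKeys <- keyOf(pos[, 1L], pos[, 2L])

  ## totals: every positive exactly once, as many negatives
  sp <- samples[samples$label == 1L, ]
  sn <- samples[samples$label == 0L, ]
  expect_setequal(keyOf(sp$drug, sp$disease), posKeys)
  expect_equal(nrow(sp), nrow(pos))
  expect_equal(nrow(sn), nrow(pos))

  ## negatives never in the positive set; no duplicates across folds
  negKeys <- keyOf(sn$drug, sn$disease)
  expect_length(intersect(negKeys, posKeys), 0L)
  expect_false(anyDuplicated(negKeys) > 0L)

  ## per-fold 1:1 ratio
  for (f in 0:4) {
    fs <- samples[samples$fold == f, ]
    expect_equal(sum(fs$label == 1L), sum(fs$label == 0L))
  }

  ## 10 positives, k = 5 -> folds of 2 positives, 20 samples total
  reg <- nodeRegistry()
  reg <- addNodes(reg, paste0("r", 1:5), "drug")
  reg <- addNodes(reg, paste0("d", 1:6), "disease")
  reg <- addNodes(reg, "g1", "gene")
  dd <- cbind(rep(1:5, each = 2L), c(6L, 7L, 8L, 9L, 10L, 6L, 7L, 8L, 9L, 10L))
  small <- buildHeteroGraph(reg, list("drug-disease" = dd))
  s <- makeFolds(small, k = 5L, seed = 1L)
  expect_equal(nrow(s), 20L)
  expect_true(all(table(s$fold, s$label) == 2L))

  ## determinism
  expect_identical(makeFolds(g, k = 5L, seed = 3L), samples)
})

test_that("metrics match brute-force oracles on random vectors", {
  ## hand-checked spot values
  m <- computeMetrics(c(0.9, 0.1), c(1, 0))
  expect_equal(unlist(m[c("aupr", "auc", "f1", "recall")]),
               c(aupr = 1, auc = 1, f1 = 1, recall = 1))
  expect_equal(computeMetrics(c(0.4, 0.4, 0.4, 0.4), c(1, 0, 1, 0))$auc, 0.5)
  expect_equal(computeMetrics(c(0.8, 0.7, 0.6, 0.4), c(1, 0, 1, 0))$auc, 0.75)
  expect_error(computeMetrics(c(0.2, 0.8), c(1, 1)), class = "geneDRMetricError")

  ## 200 random vectors (with ties) vs exhaustive oracles
  set.seed(123)
  for (i in 1:200) {
    n <- sample(4:30, 1L)
    labels <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(labels)) < 2L) labels[1:2] <- c(0L, 1L)
    scores <- if (i %% 3 == 0L) sample(seq(0, 1, by = 0.25), n, replace = TRUE)
              else runif(n)
    m <- computeMetrics(scores, labels)
    expect_identical(m$auc, aucOracle(scores, labels))
    expect_equal(m$aupr, auprOracle(scores, labels), tolerance = 1e-9)
  }
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  scores <- runif(40)
  labels <- rbinom(40, 1, 0.5)
  labels[1:2] <- c(0L, 1L)
  expect_equal(computeMetrics(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("cross-validation matches a hand-scripted per-fold loop", {
  g <- studyFixture()$graph
  cfg <- genedrConfig(hidden = 8L, gcn_layers = 2L, epochs = 8L, variant = "no_gmp",
                      patience = Inf, val_fraction = 0, transe_epochs = 20L,
                      k_folds = 2L, seed = 5L)
  cv <- crossValidate(g, cfg)
  expect_equal(nrow(cv$per_fold), 2L)
  expect_equal(unname(cv$mean["auc"]), mean(cv$per_fold$auc))

  ## oracle loop with the same shared inputs and seeds
  samples <- makeFolds(g, k = 2L, seed = cfg$seed)
  st <- trainTransE(buildTripleSet(graphView(g, "DGD")), g, d = cfg$hidden,
                    epochs = cfg$transe_epochs, lr = cfg$transe_lr,
                    margin = cfg$transe_margin, norm_order = cfg$transe_norm,
                    seed = cfg$seed)
  Ht <- embeddingMatrix(st@entity)
  for (f in 0:1) {
    tr <- samples[samples$fold != f, ]
    te <- samples[samples$fold == f, ]
    model <- trainGeneDR(g, tr, cfg, Htranse = Ht, pathSet = NULL)
    pos <- as.matrix(tr[tr$label == 1L, c("drug", "disease")])
    Ahat <- normalizeAdjacency(rbind(pos, relationEdges(g, "drug-gene"),
                                     relationEdges(g, "disease-gene"),
                                     relationEdges(g, "gene-gene")), n = nodeCount(g))
    sc <- predictPairs(model, g, Ahat, NULL, Ht, as.matrix(te[, c("drug", "disease")]))
    m <- computeMetrics(sc, te$label)
    expect_equal(cv$per_fold$auc[cv$per_fold$fold == f], m$auc, tolerance = 1e-12)
    expect_equal(cv$per_fold$aupr[cv$per_fold$fold == f], m$aupr, tolerance = 1e-12)
  }
})

test_that("no test-fold positive enters the training adjacency", {
  g <- studyFixture()$graph
  samples <- makeFolds(g, k = 5L, seed = 2L)
  for (f in 0:4) {
    tr <- samples[samples$fold != f, ]
    te <- samples[samples$fold == f & samples$label == 1L, ]
    Ahat <- normalizeAdjacency(as.matrix(tr[tr$label == 1L, c("drug", "disease")]),
                               n = nodeCount(g))
    for (i in seq_len(nrow(te)))
      expect_identical(Ahat[te$drug[i], te$disease[i]], 0)
  }
})
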