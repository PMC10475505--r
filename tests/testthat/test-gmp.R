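test_that("path encoding matches a hand-unrolled recurrence and LSTM fixed points", {
  g <- chainGraph()
  d <- 2L
  par <- gmpParams(d, seed = 4L)
  H <- withr::with_seed(8, matrix(rnorm(nodeCount(g) * d), nodeCount(g), d))

  ## zero weights -> zero output for any path
  zpar <- par
  zpar$enc$Wx[] <- 0; zpar$enc$Wh[] <- 0; zpar$enc$b[] <- 0
  expect_equal(encodePath(zpar, 1L, c(3L, 4L), H), c(0, 0))

  ## identical sequences -> identical encodings
  expect_identical(encodePath(par, 1L, c(3L, 4L), H), encodePath(par, 1L, c(3L, 4L), H))

  ## 2-gene path against the scalar gate-equation oracle; the fed sequence
  ## is genes reversed then the anchor
  genes <- c(3L, 4L)
  xs <- lapply(c(rev(genes), 1L), function(i) H[i, , drop = FALSE])
  expect_equal(encodePath(par, 1L, genes, H),
               lstmUnrollOracle(par$enc$Wx, par$enc$Wh, par$enc$b, xs),
               tolerance = 1e-12)
})

test_that("attention weights are a proper softmax over path scores", {
  g <- toyGraph()
  d <- 4L
  par <- gmpParams(d, seed = 2L)
  H <- withr::with_seed(1, matrix(rnorm(nodeCount(g) * d), nodeCount(g), d))

  ## singleton path -> weight exactly 1, message = encoding
  one <- aggregateMessages(par, 1L, list(7L), H)
  expect_identical(one$weights, 1)
  expect_equal(one$message, encodePath(par, 1L, 7L, H))

  ## two identical paths -> (0.5, 0.5)
  two <- aggregateMessages(par, 1L, list(7L, 7L), H)
  expect_equal(two$weights, c(0.5, 0.5))

  ## hand-set scorer with scores (0, ln2, ln4) -> weights (1/7, 2/7, 4/7)
  paths <- list(7L, c(7L, 8L), c(7L, 8L, 9L))
  E <- t(vapply(paths, function(p) encodePath(par, 1L, p, H), numeric(d)))
  target <- c(0, log(2), log(4))
  ## pick a scorer vector that realizes exactly these three scores
  A <- rbind(E, withr::with_seed(10, rnorm(d)))
  w <- solve(A, c(target, 0))
  hpar <- par
  hpar$w_att <- w
  agg <- aggregateMessages(hpar, 1L, paths, H)
  expect_equal(agg$weights, c(1, 2, 4) / 7, tolerance = 1e-8)
  expect_equal(agg$message, drop(crossprod(E, c(1, 2, 4) / 7)), tolerance = 1e-8)

  ## empty path set -> zero message
  none <- aggregateMessages(par, 1L, list(), H)
  expect_equal(none$message, numeric(d))
})

test_that("gmpUpdate passes genes through, keeps pathless anchors in test mode, and matches the naive composition", {
  sim <- studyFixture()
  g <- sim$graph
  d <- 6L
  ps <- extractGenePaths(graphView(g, "DGD"), K_max = 5L, n_tries = 30L, seed = 7L)
  par <- gmpParams(d, seed = 3L)
  H <- withr::with_seed(2, matrix(rnorm(nodeCount(g) * d), nodeCount(g), d))
  out <- gmpUpdate(par, ps, embeddingMatrix(H), g)
  expect_s4_class(out, "EmbeddingMatrix")
  expect_equal(embStage(out), "GMP")
  M <- embMatrix(out)

  ## gene rows pass through exactly
  genes <- nodesOfType(g, "gene")
  expect_identical(M[genes, ], H[genes, ])

  ## anchor rows equal the naive per-anchor composition of the public ops
  anchors <- c(nodesOfType(g, "drug"), nodesOfType(g, "disease"))
  for (a in anchors[c(1L, 5L, 21L, 40L)]) {
    m <- aggregateMessages(par, a, anchorPaths(ps, a), H)$message
    expect_equal(M[a, ], drop(tanh(c(H[a, ], m) %*% par$Wu + par$bu)), tolerance = 1e-10)
  }

  ## identity-update test mode: W_u = [I ; 0], b = 0 leaves a pathless
  ## anchor's row unchanged
  reg <- starGraph()@registry
  star <- starGraph()
  ps0 <- extractGenePaths(graphView(star, "DGD"), K_max = 5L, n_tries = 20L, seed = 1L)
  ipar <- gmpParams(d, seed = 1L, activation = "identity")
  ipar$Wu <- rbind(diag(d), matrix(0, d, d))
  ipar$bu[] <- 0
  H2 <- withr::with_seed(3, matrix(rnorm(nodeCount(star) * d), nodeCount(star), d))
  M2 <- embMatrix(gmpUpdate(ipar, ps0, embeddingMatrix(H2), star))
  expect_equal(M2[2L, ], H2[2L, ])  # disease anchor has no paths

  ## non-finite input rejected
  Hbad <- H; Hbad[1L, 1L] <- NA_real_
  expect_error(gmpUpdate(par, ps, Hbad, g), class = "geneDRValidationError")
})

test_that("messages are permutation invariant and weights sum to one", {
  sim <- studyFixture()
  g <- sim$graph
  d <- 5L
  par <- gmpParams(d, seed = 9L)
  H <- withr::with_seed(4, matrix(rnorm(nodeCount(g) * d), nodeCount(g), d))
  ps <- extractGenePaths(graphView(g, "DGD"), K_max = 8L, n_tries = 50L, seed = 2L)
  anchors <- names(ps@paths)[vapply(ps@paths, length, 0L) >= 3L]
  for (a in as.integer(anchors[1:8])) {
    paths <- anchorPaths(ps, a)
    agg <- aggregateMessages(par, a, paths, H)
    expect_true(all(agg$weights >= 0))
    expect_equal(sum(agg$weights), 1, tolerance = 1e-6)
    perm <- withr::with_seed(a, sample(length(paths)))
    agg2 <- aggregateMessages(par, a, paths[perm], H)
    expect_equal(agg2$message, agg$message, tolerance = 1e-6)
  }
})

test_that("batched forward equals the naive per-anchor loop and gradients check numerically", {
  sim <- studyFixture()
  g <- sim$graph
  d <- 3L
  par <- gmpParams(d, seed = 5L)
  ps <- extractGenePaths(graphView(g, "DGD"), K_max = 4L, n_tries = 30L, seed = 3L)
  H <- withr::with_seed(5, matrix(rnorm(nodeCount(g) * d), nodeCount(g), d))
  anchors <- c(nodesOfType(g, "drug"), nodesOfType(g, "disease"))
  fw <- geneDR:::gmpForwardCore(par, ps, H, anchors, want_cache = TRUE)
  ## naive loop oracle over all anchors
  for (a in anchors) {
    m <- aggregateMessages(par, a, anchorPaths(ps, a), H)$message
    expect_equal(fw$H[a, ], drop(tanh(c(H[a, ], m) %*% par$Wu + par$bu)),
                 tolerance = 1e-5)
  }
  ## numeric gradient of a scalar functional through the batched backward
  w <- withr::with_seed(6, rnorm(d))
  dOut <- outer(drop(cos(fw$H %*% w)), w)
  bw <- geneDR:::gmpBackwardCore(par, fw$cache, dOut)
  lossW <- function(v) {
    p2 <- par; p2$w_att <- v
    sum(sin(geneDR:::gmpForwardCore(p2, ps, H, anchors)$H %*% w))
  }
  expect_equal(bw$grads$w_att, numGrad(lossW, par$w_att), tolerance = 1e-5)
  lossWu <- function(v) {
    p2 <- par; p2$Wu[, 1L] <- v
    sum(sin(geneDR:::gmpForwardCore(p2, ps, H, anchors)$H %*% w))
  }
  expect_equal(bw$grads$Wu[, 1L], numGrad(lossWu, par$Wu[, 1L]), tolerance = 1e-5)
})
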