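## Internal neural primitives: batched LSTM and chain-GCN path encoders
## with analytic backprop, a 2-layer predictor head, and Adam. Gate layout
## of the combined LSTM weight matrices is [input | forget | output | cell]
## column blocks. All forward functions cache what the matching backward
## needs; backward functions return parameter gradients plus gradients with
## respect to the inputs so the whole model is differentiable end to end.

## ---- LSTM ---------------------------------------------------------------

lstmInit <- function(d) {
  b <- numeric(4L * d)
  b[(d + 1L):(2L * d)] <- 1  # forget-gate bias at 1: standard stabilization
  list(type = "lstm", Wx = initW(d, 4L * d), Wh = initW(d, 4L * d), b = b)
}

## Xs: list over time steps of (B x d) input matrices. Returns final hidden
## state (B x d) plus cache for BPTT.
lstmForward <- function(par, Xs) {
  Tn <- length(Xs)
  B <- nrow(Xs[[1L]]); d <- ncol(Xs[[1L]])
  idx <- list(i = 1:d, f = (d + 1L):(2L * d), o = (2L * d + 1L):(3L * d), g = (3L * d + 1L):(4L * d))
  H <- C <- matrix(0, B, d)
  steps <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    Z <- Xs[[t]] %*% par$Wx + H %*% par$Wh + rep(par$b, each = B)
    I <- sigmoid(Z[, idx$i, drop = FALSE]); Fg <- sigmoid(Z[, idx$f, drop = FALSE])
    O <- sigmoid(Z[, idx$o, drop = FALSE]); G <- tanh(Z[, idx$g, drop = FALSE])
    Cprev <- C
    C <- Fg * Cprev + I * G
    tC <- tanh(C)
    steps[[t]] <- list(I = I, Fg = Fg, O = O, G = G, Cprev = Cprev, tC = tC, Hprev = H)
    H <- O * tC
  }
  list(E = H, cache = list(steps = steps, Xs = Xs))
}

lstmBackward <- function(par, cache, dE) {
  steps <- cache$steps; Xs <- cache$Xs
  Tn <- length(steps)
  d <- ncol(dE)
  dWx <- matrix(0, d, 4L * d); dWh <- matrix(0, d, 4L * d); db <- numeric(4L * d)
  dXs <- vector("list", Tn)
  dH <- dE
  dC <- matrix(0, nrow(dE), d)
  for (t in rev(seq_len(Tn))) {
    s <- steps[[t]]
    dO <- dH * s$tC
    dCt <- dC + dH * s$O * (1 - s$tC^2)
    dI <- dCt * s$G
    dF <- dCt * s$Cprev
    dG <- dCt * s$I
    dZ <- cbind(dI * s$I * (1 - s$I), dF * s$Fg * (1 - s$Fg),
                dO * s$O * (1 - s$O), dG * (1 - s$G^2))
    dWx <- dWx + crossprod(Xs[[t]], dZ)
    dWh <- dWh + crossprod(s$Hprev, dZ)
    db <- db + colSums(dZ)
    dXs[[t]] <- tcrossprod(dZ, par$Wx)
    dH <- tcrossprod(dZ, par$Wh)
    dC <- dCt * s$Fg
  }
  list(grads = list(Wx = dWx, Wh = dWh, b = db), dXs = dXs)
}

## ---- chain-GCN path encoder (the no_lstm ablation) ----------------------

pgcnInit <- function(d) list(type = "pgcn", Wp = initW(d, d), bp = numeric(d))

## Symmetric-normalized chain adjacency with self-loops for a path of Tn nodes.
chainAhat <- function(Tn) {
  A <- diag(Tn)
  if (Tn > 1L) for (t in seq_len(Tn - 1L)) A[t, t + 1L] <- A[t + 1L, t] <- 1
  dinv <- 1 / sqrt(rowSums(A))
  A * tcrossprod(dinv)
}

## One GCN layer on the chain, tanh, mean-pooled over the Tn nodes.
pgcnForward <- function(par, Xs) {
  Tn <- length(Xs)
  Ahat <- chainAhat(Tn)
  Ms <- lapply(seq_len(Tn), function(t) {
    M <- 0
    for (s in seq_len(Tn)) if (Ahat[t, s] != 0) M <- M + Ahat[t, s] * Xs[[s]]
    M
  })
  Acts <- lapply(Ms, function(M) tanh(M %*% par$Wp + rep(par$bp, each = nrow(M))))
  E <- Reduce(`+`, Acts) / Tn
  list(E = E, cache = list(Ms = Ms, Acts = Acts, Ahat = Ahat))
}

pgcnBackward <- function(par, cache, dE) {
  Tn <- length(cache$Ms)
  d <- ncol(dE)
  dWp <- matrix(0, d, d); dbp <- numeric(d)
  dMs <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    dPre <- (dE / Tn) * (1 - cache$Acts[[t]]^2)
    dWp <- dWp + crossprod(cache$Ms[[t]], dPre)
    dbp <- dbp + colSums(dPre)
    dMs[[t]] <- tcrossprod(dPre, par$Wp)
  }
  dXs <- vector("list", Tn)
  for (s in seq_len(Tn)) {
    dX <- 0
    for (t in seq_len(Tn)) if (cache$Ahat[t, s] != 0) dX <- dX + cache$Ahat[t, s] * dMs[[t]]
    dXs[[s]] <- dX
  }
  list(grads = list(Wp = dWp, bp = dbp), dXs = dXs)
}

## ---- encoder dispatch ---------------------------------------------------

encForward <- function(par, Xs) {
  if (par$type == "lstm") lstmForward(par, Xs) else pgcnForward(par, Xs)
}

encBackward <- function(par, cache, dE) {
  if (par$type == "lstm") lstmBackward(par, cache, dE) else pgcnBackward(par, cache, dE)
}

encZeroGrads <- function(par) {
  if (par$type == "lstm") list(Wx = 0 * par$Wx, Wh = 0 * par$Wh, b = 0 * par$b)
  else list(Wp = 0 * par$Wp, bp = 0 * par$bp)
}

## ---- predictor head -----------------------------------------------------

predInit <- function(d, hidden = TRUE) {
  if (hidden) list(hidden = TRUE, W1 = initW(2L * d, d), b1 = numeric(d),
                   w2 = initW(d, 1L), b2 = 0)
  else list(hidden = FALSE, w2 = initW(2L * d, 1L), b2 = 0)
}

predForward <- function(par, H, pairs) {
  X <- cbind(H[pairs[, 1L], , drop = FALSE], H[pairs[, 2L], , drop = FALSE])
  if (isTRUE(par$hidden)) {
    Hp <- relu(X %*% par$W1 + rep(par$b1, each = nrow(X)))
    z <- drop(Hp %*% par$w2) + par$b2
  } else {
    Hp <- NULL
    z <- drop(X %*% par$w2) + par$b2
  }
  list(p = sigmoid(z), z = z, cache = list(X = X, Hp = Hp, pairs = pairs))
}

## dz: gradient wrt the logit, length B. Returns grads + dH (n x d).
predBackward <- function(par, cache, dz, n) {
  X <- cache$X
  if (isTRUE(par$hidden)) {
    dHp <- tcrossprod(dz, par$w2) * (cache$Hp > 0)
    grads <- list(W1 = crossprod(X, dHp), b1 = colSums(dHp),
                  w2 = crossprod(cache$Hp, dz), b2 = sum(dz))
    dX <- tcrossprod(dHp, par$W1)
  } else {
    grads <- list(w2 = crossprod(X, dz), b2 = sum(dz))
    dX <- dz %*% t(par$w2)
  }
  d <- ncol(X) %/% 2L
  dH <- matrix(0, n, d)
  dH <- scatterAdd(dH, cache$pairs[, 1L], dX[, seq_len(d), drop = FALSE])
  dH <- scatterAdd(dH, cache$pairs[, 2L], dX[, d + seq_len(d), drop = FALSE])
  list(grads = grads, dH = dH)
}

## ---- Adam ---------------------------------------------------------------

adamInit <- function(params) {
  list(m = mapParams(function(x) 0 * x, params),
       v = mapParams(function(x) 0 * x, params),
       t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- mapParams(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- mapParams(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- mapParams(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps), state$m, state$v)
  params <- mapParams(function(p, u) p - lr * u, params, upd)
  list(params = params, state = state)
}

addGrads <- function(a, b) mapParams(`+`, a, b)
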