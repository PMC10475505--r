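## Internal numerical / RNG helpers shared across modules.

## Evaluate expr under a temporary seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

## Accumulate rows of `add` (m x d) into rows `idx` of `target` (n x d),
## summing over repeated indices.
scatterAdd <- function(target, idx, add) {
  if (length(idx) == 0L) return(target)
  agg <- rowsum(add, group = idx, reorder = FALSE)
  rows <- as.integer(rownames(agg))
  target[rows, ] <- target[rows, , drop = FALSE] + agg
  target
}

## Glorot-uniform weight init.
initW <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

## Elementwise-walk two parallel nested lists of matrices/vectors.
## Non-numeric leaves (structure flags like the encoder type) pass through.
mapParams <- function(f, a, b = NULL) {
  if (is.list(a)) {
    nm <- names(a)
    out <- lapply(seq_along(a), function(i) {
      bi <- if (is.null(b)) NULL
            else if (!is.null(nm) && !is.null(names(b))) b[[nm[i]]]
            else b[[i]]
      mapParams(f, a[[i]], bi)
    })
    names(out) <- nm
    out
  } else if (!is.numeric(a)) a
  else if (is.null(b)) f(a) else f(a, b)
}

## Sum of f over all numeric leaves of a nested list.
sumParams <- function(f, a) {
  if (is.list(a)) sum(vapply(a, function(x) sumParams(f, x), 0))
  else if (!is.numeric(a)) 0
  else f(a)
}

stopIfNot <- function(cond, msg, class = "geneDRError") {
  if (!cond) stop(errorCondition(msg, class = c(class, "error", "condition")))
  invisible(TRUE)
}
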