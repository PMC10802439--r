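## Internal neural-network engine for the two GNN modules: per-node
## embedding tables, K mean/sum-aggregation message-passing layers, a
## two-layer feedforward head, manual reverse-mode gradients and Adam.
## Parameters live in flat named lists so the optimizer and the
## freeze/snapshot logic in the trainer stay trivial.

defaultModelConfig <- function(K = 1L, d = 16L, B = 5L, hidden = 2L * d,
                               aggregator = c("mean", "sum"), seed = 1L) {
  aggregator <- match.arg(aggregator)
  list(K = as.integer(K), d = as.integer(d), B = as.integer(B),
       hidden = as.integer(hidden), aggregator = aggregator,
       seed = as.integer(seed))
}

## Xavier-style init for weights; embeddings N(0, 1/sqrt(d)).
initNet <- function(kind, nodes, thresholds, config) {
  n <- length(nodes); d <- config$d; B <- config$B; w <- 3L * d
  h <- config$hidden; K <- config$K
  rmat <- function(r, c, sd) matrix(stats::rnorm(r * c, 0, sd), r, c)
  withSeed(config$seed, {
    par <- list()
    esd <- 1 / sqrt(d)
    if (kind == "response") {
      par$flag0 <- rmat(n, d, esd)
      par$flag1 <- rmat(n, d, esd)
      par$bin <- rmat(n * B, d, esd)
    } else {
      par$bin <- rmat(n * B, d, esd)   # diseased-state bins
      par$binT <- rmat(n * B, d, esd)  # treated-state bins
    }
    par$pos <- rmat(n, d, esd)
    for (k in seq_len(K)) {
      sd <- sqrt(2 / (2 * w))
      par[[paste0("Wself", k)]] <- rmat(w, w, sd)
      par[[paste0("Wnei", k)]] <- rmat(w, w, sd)
      par[[paste0("b", k)]] <- numeric(w)
    }
    par$V1 <- rmat(h, w, sqrt(2 / w))
    par$c1 <- numeric(h)
    par$V2 <- rmat(1, h, sqrt(2 / h))
    par$c2 <- 0
    list(kind = kind, nodes = nodes, thr = thresholds, config = config,
         par = par)
  })
}

## Bin index in 1..B per value: 1 + number of per-gene thresholds strictly
## below the value; constant genes (all thresholds equal) land in bin 1.
binIndices <- function(x, thr, B) {
  cnt <- matrix(0L, nrow(x), ncol(x))
  for (k in seq_len(B - 1L)) cnt <- cnt + (x > thr[, k])
  cnt + 1L
}

## Row-normalized (mean) or raw (sum) in-neighbor adjacency operator:
## row i aggregates over parents j (arcs j -> i).
buildAdj <- function(g, aggregator = "mean") {
  n <- numNodes(g); a <- g@arcs
  A <- Matrix::sparseMatrix(i = a[, 2L], j = a[, 1L], x = 1, dims = c(n, n))
  if (aggregator == "mean") {
    deg <- Matrix::rowSums(A)
    A <- Matrix::Diagonal(x = ifelse(deg > 0, 1 / deg, 0)) %*% A
  }
  methods::as(A, "CsparseMatrix")
}

## Replicate an n x n aggregation operator across S samples as a sparse
## block-diagonal (sample-level) operator matching sample-major feature rows
## (row (s-1)*n + i is node i of sample s).
expandAdj <- function(A, S) {
  if (S == 1L) A else Matrix::kronecker(Matrix::Diagonal(S), A)
}

## Sample-level aggregation: one sparse-dense product for the whole batch.
graphMultiply <- function(A, H) as.matrix(A %*% H)

## --- forward -------------------------------------------------------------

## Features for f_r: flag interpolation || expression bin || positional.
## x, flags: n x S matrices. Returns (S*n) x 3d plus the caches backward needs.
encodeResponseFeatures <- function(net, x, flags) {
  n <- length(net$nodes); S <- ncol(x); B <- net$config$B
  iIdx <- rep.int(seq_len(n), S)
  fv <- as.vector(flags)
  bins <- as.vector(binIndices(x, net$thr, B))
  H0 <- cbind((1 - fv) * net$par$flag0[iIdx, , drop = FALSE] +
                fv * net$par$flag1[iIdx, , drop = FALSE],
              net$par$bin[(iIdx - 1L) * B + bins, , drop = FALSE],
              net$par$pos[iIdx, , drop = FALSE])
  list(H0 = H0, iIdx = iIdx, fv = fv, bins = bins)
}

## Features for f_p: diseased bin || treated bin || positional.
encodePerturbagenFeatures <- function(net, xd, xt) {
  n <- length(net$nodes); S <- ncol(xd); B <- net$config$B
  iIdx <- rep.int(seq_len(n), S)
  binsD <- as.vector(binIndices(xd, net$thr, B))
  binsT <- as.vector(binIndices(xt, net$thr, B))
  H0 <- cbind(net$par$bin[(iIdx - 1L) * B + binsD, , drop = FALSE],
              net$par$binT[(iIdx - 1L) * B + binsT, , drop = FALSE],
              net$par$pos[iIdx, , drop = FALSE])
  list(H0 = H0, iIdx = iIdx, binsD = binsD, binsT = binsT)
}

## GNN stack + head. A is the sample-level aggregation operator (see
## expandAdj; n x n for a single sample). Returns per-node head outputs
## (length S*n) and caches.
netForward <- function(net, A, H0) {
  K <- net$config$K
  p <- net$par
  Hs <- vector("list", K + 1L); Ms <- vector("list", K)
  Ps <- vector("list", K)
  Hs[[1L]] <- H0
  N <- nrow(H0)
  for (k in seq_len(K)) {
    M <- graphMultiply(A, Hs[[k]])
    P <- tcrossprod(Hs[[k]], p[[paste0("Wself", k)]]) +
      tcrossprod(M, p[[paste0("Wnei", k)]])
    P <- P + rep(p[[paste0("b", k)]], each = N)
    Hs[[k + 1L]] <- P * (P > 0)
    Ms[[k]] <- M; Ps[[k]] <- P
  }
  Z <- Hs[[K + 1L]]
  P1 <- tcrossprod(Z, p$V1) + rep(p$c1, each = N)
  Hd <- P1 * (P1 > 0)
  out <- as.vector(tcrossprod(Hd, p$V2)) + p$c2
  list(out = out, Z = Z, Hs = Hs, Ms = Ms, Ps = Ps, P1 = P1, Hd = Hd)
}

## --- backward ------------------------------------------------------------

## Backprop dL/d(out) through head and GNN stack. Returns dH0 and, when
## wantParamGrads, the parameter gradient list (embedding grads excluded --
## the encoder-specific backward adds those).
netBackward <- function(net, A, fw, dOut, wantParamGrads = TRUE) {
  K <- net$config$K
  p <- net$par
  g <- if (wantParamGrads) list() else NULL
  dOut <- matrix(dOut, ncol = 1L)
  if (wantParamGrads) {
    g$V2 <- crossprod(dOut, fw$Hd)
    g$c2 <- sum(dOut)
  }
  dHd <- dOut %*% p$V2
  dP1 <- dHd * (fw$P1 > 0)
  if (wantParamGrads) {
    g$V1 <- crossprod(dP1, fw$Z)
    g$c1 <- colSums(dP1)
  }
  dH <- dP1 %*% p$V1
  At <- Matrix::t(A)
  for (k in rev(seq_len(K))) {
    dP <- dH * (fw$Ps[[k]] > 0)
    if (wantParamGrads) {
      g[[paste0("Wself", k)]] <- crossprod(dP, fw$Hs[[k]])
      g[[paste0("Wnei", k)]] <- crossprod(dP, fw$Ms[[k]])
      g[[paste0("b", k)]] <- colSums(dP)
    }
    dM <- dP %*% p[[paste0("Wnei", k)]]
    dH <- dP %*% p[[paste0("Wself", k)]] + graphMultiply(At, dM)
  }
  list(dH0 = dH, grads = g)
}

## Scatter-add rows of `m` grouped by `grp` into a template of `rows` rows.
scatterRows <- function(m, grp, rows) {
  rs <- rowsum(m, grp)
  out <- matrix(0, rows, ncol(m))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

## Embedding gradients for the f_r encoder; also returns dL/d(flags),
## needed when soft flags carry gradients from the cycle loss.
encodeResponseBackward <- function(net, enc, dH0, wantParamGrads = TRUE) {
  d <- net$config$d; B <- net$config$B; n <- length(net$nodes)
  g1 <- dH0[, seq_len(d), drop = FALSE]
  g2 <- dH0[, d + seq_len(d), drop = FALSE]
  g3 <- dH0[, 2L * d + seq_len(d), drop = FALSE]
  dFlags <- rowSums(g1 * (net$par$flag1[enc$iIdx, , drop = FALSE] -
                            net$par$flag0[enc$iIdx, , drop = FALSE]))
  g <- NULL
  if (wantParamGrads) {
    g <- list(
      flag0 = scatterRows((1 - enc$fv) * g1, enc$iIdx, n),
      flag1 = scatterRows(enc$fv * g1, enc$iIdx, n),
      bin = scatterRows(g2, (enc$iIdx - 1L) * B + enc$bins, n * B),
      pos = scatterRows(g3, enc$iIdx, n))
  }
  list(grads = g, dFlags = dFlags)
}

encodePerturbagenBackward <- function(net, enc, dH0) {
  d <- net$config$d; B <- net$config$B; n <- length(net$nodes)
  list(grads = list(
    bin = scatterRows(dH0[, seq_len(d), drop = FALSE],
                      (enc$iIdx - 1L) * B + enc$binsD, n * B),
    binT = scatterRows(dH0[, d + seq_len(d), drop = FALSE],
                       (enc$iIdx - 1L) * B + enc$binsT, n * B),
    pos = scatterRows(dH0[, 2L * d + seq_len(d), drop = FALSE],
                      enc$iIdx, n)))
}

## --- optimizer -----------------------------------------------------------

adamInit <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0L)
}

adamStep <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    par[[nm]] <- par[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = state)
}

sumGrads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}
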