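## Dual training loop: interleaved per-epoch updates of f_r and f_p (f_r
## frozen inside the f_p step), independent early stopping per module,
## and the GNN-depth grid search.

#' Training configuration
#'
#' @param lossMode f_p objective: `"supercycle"` (default), `"super"` or
#'   `"cycle"` (see [lossPerturbagen()]).
#' @param maxEpochs maximum number of epochs.
#' @param patience early-stopping patience in epochs (default 15).
#' @param minDelta minimum validation-loss improvement (default 1e-5).
#' @param learningRate Adam learning rate (default 0.01; full-batch training
#'   on desk-scale data).
#' @param batchSize minibatch size; `NULL` (default) trains full-batch.
#' @param KGrid GNN-depth grid for [gridSearchK()] (default `c(1, 2, 3)`).
#' @param useDiseaseData also train f_r on disease triplets when available.
#' @param K,d,B,hidden,aggregator model architecture (see [responseModel()]).
#' @param seed root seed; model inits and splits derive child seeds from it.
#' @return a `TrainConfig` list.
#' @export
trainConfig <- function(lossMode = c("supercycle", "super", "cycle"),
                        maxEpochs = 200L, patience = 15L, minDelta = 1e-5,
                        learningRate = 0.01, batchSize = NULL,
                        KGrid = c(1L, 2L, 3L), useDiseaseData = TRUE,
                        K = 1L, d = 16L, B = 5L, hidden = 2L * d,
                        aggregator = "mean", seed = 1L) {
  lossMode <- match.arg(lossMode)
  stopifnot(patience >= 1L, minDelta >= 0, maxEpochs >= 1L, length(KGrid) >= 1L)
  structure(list(lossMode = lossMode, maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience), minDelta = minDelta,
                 learningRate = learningRate, batchSize = batchSize,
                 KGrid = as.integer(KGrid), useDiseaseData = useDiseaseData,
                 K = as.integer(K), d = as.integer(d), B = as.integer(B),
                 hidden = as.integer(hidden), aggregator = aggregator,
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

## One packed supervised batch for f_r over a sample index set: samples
## sharing an intervention set share a mutilated adjacency; the per-sample
## operators are stacked block-diagonally so the whole batch is a single
## forward/backward pass. Embedding gather indices are precomputed once per
## batch (thresholds are fixed during a fit).
buildFrBatch <- function(g, datasets, idxList, aggregator, thr = NULL,
                         B = NULL) {
  xs <- list(); ts <- list(); fs <- list(); As <- list()
  for (di in seq_along(datasets)) {
    dataset <- datasets[[di]]; idx <- idxList[[di]]
    if (!length(idx)) next
    cd <- SummarizedExperiment::colData(dataset)
    key <- paste(cd$kind[idx], cd$targets[idx])
    init <- initialState(dataset); outc <- outcomeState(dataset)
    nodes <- rownames(init)
    for (ix in split(idx, key)) {
      u <- strsplit(cd$targets[ix[1L]], ",")[[1L]]
      flags <- matrix(0, nrow(init), length(ix))
      flags[match(u, nodes), ] <- 1
      xs[[length(xs) + 1L]] <- init[, ix, drop = FALSE]
      ts[[length(ts) + 1L]] <- outc[, ix, drop = FALSE]
      fs[[length(fs) + 1L]] <- flags
      As[[length(As) + 1L]] <- expandAdj(buildAdj(mutilate(g, u), aggregator),
                                         length(ix))
    }
  }
  if (!length(xs)) return(NULL)
  x <- do.call(cbind, xs)
  batch <- list(A = methods::as(Matrix::bdiag(As), "CsparseMatrix"),
                x = x, target = do.call(cbind, ts),
                flags = do.call(cbind, fs), n = ncol(x))
  if (!is.null(thr)) {
    batch$iIdx <- rep.int(seq_len(nrow(x)), ncol(x))
    batch$bins <- as.vector(binIndices(x, thr, B))
    batch$fv <- as.vector(batch$flags)
    batch$targetVec <- as.vector(batch$target)
  }
  batch
}

## Mean response CE over the batch; optionally the gradient. Compiled path.
frEpoch <- function(net, batch, wantGrad = TRUE) {
  st <- .frStepCpp(batch$A, batch$iIdx, batch$bins, batch$fv, net$par,
                   net$config$K, net$config$B, batch$targetVec,
                   wantGrad, FALSE)
  list(loss = st$loss, grads = if (wantGrad) st$grads else NULL)
}

## Pure-R reference of the f_r step (loss only); retained as an independent
## route for consistency tests and diagnostics.
frEpochR <- function(net, batch) {
  n <- length(net$nodes); S <- batch$n
  fwd <- responseForwardMatrix(net, batch$A, batch$x, batch$flags)
  p <- pmin(1 - CLIP_EPS, pmax(CLIP_EPS, fwd$pred))
  list(loss = -sum(batch$target * log(p) +
                     (1 - batch$target) * log(1 - p)) / (S * n))
}

## f_p objective on a sample block (shared intact adjacency). Supervision is
## weighted binary CE on the scores; the cycle term runs the *frozen* f_r on
## soft flags sigmoid(scores) over the intact graph, so gradients reach f_p
## through the flag-embedding interpolation only. Compiled path; `data` is a
## prepared buildFpData() block carrying its expanded operator in `A`.
fpEpoch <- function(netFp, netFr, data, mode, wantGrad = TRUE) {
  modeInt <- match(mode, c("super", "cycle", "supercycle")) - 1L
  st <- .fpStepCpp(data$A, data$iIdx, data$binsD, data$binsT, netFp$par,
                   netFr$par, netFp$config$K, netFr$config$K,
                   netFp$config$B, data$yIndVec, data$wtsVec,
                   as.vector(data$xd), as.vector(data$xt), modeInt,
                   wantGrad, FALSE)
  list(loss = st$loss, supervision = st$supervision, cycle = st$cycle,
       grads = if (wantGrad) st$grads else NULL)
}

## Pure-R reference of the f_p objective (loss only); independent route for
## consistency tests.
fpEpochR <- function(netFp, netFr, data, mode) {
  S <- ncol(data$xd); n <- nrow(data$xd)
  fwd <- perturbagenForwardMatrix(netFp, data$A, data$xd, data$xt)
  sig <- logistic(fwd$scores)
  supLoss <- cycLoss <- NA_real_
  if (mode != "cycle") {
    p <- pmin(1 - CLIP_EPS, pmax(CLIP_EPS, sig))
    supLoss <- mean(-data$wts * (data$yInd * log(p) +
                                   (1 - data$yInd) * log(1 - p)))
  }
  if (mode != "super") {
    fwdR <- responseForwardMatrix(netFr, data$A, data$xd, sig)
    p <- pmin(1 - CLIP_EPS, pmax(CLIP_EPS, fwdR$pred))
    cycLoss <- mean(-(data$xt * log(p) + (1 - data$xt) * log(1 - p)))
  }
  list(loss = sum(c(supLoss, cycLoss), na.rm = TRUE), supervision = supLoss,
       cycle = cycLoss)
}

## f_p tensors for a sample index set (with precomputed gather indices when
## thresholds are supplied).
buildFpData <- function(dataset, idx, thr = NULL, B = NULL) {
  init <- initialState(dataset); outc <- outcomeState(dataset)
  n <- nrow(init)
  targets <- interventionSets(dataset)[idx]
  nodes <- rownames(init)
  yInd <- matrix(0, n, length(idx))
  wts <- matrix(1, n, length(idx))
  for (s in seq_along(idx)) {
    rows <- match(targets[[s]], nodes)
    yInd[rows, s] <- 1
    wts[rows, s] <- n / length(rows)
  }
  out <- list(xd = init[, idx, drop = FALSE], xt = outc[, idx, drop = FALSE],
              yInd = yInd, wts = wts)
  if (!is.null(thr)) {
    out$iIdx <- rep.int(seq_len(n), length(idx))
    out$binsD <- as.vector(binIndices(out$xd, thr, B))
    out$binsT <- as.vector(binIndices(out$xt, thr, B))
    out$yIndVec <- as.vector(yInd)
    out$wtsVec <- as.vector(wts)
  }
  out
}

## Early-stopping bookkeeping: first evaluation always counts as an
## improvement (best starts at Inf); the counter resets exactly when the
## improvement is >= minDelta.
esUpdate <- function(es, val, par, minDelta, patience) {
  if (es$best - val >= minDelta) {
    es$best <- val; es$bestPar <- par; es$counter <- 0L
  } else {
    es$counter <- es$counter + 1L
    if (es$counter >= patience) es$active <- FALSE
  }
  es
}

#' Train the response and discovery modules
#'
#' Runs the dual loop: per epoch, one full-batch Adam update of f_r on its
#' cross-entropy objective (over treatment and, optionally, disease
#' triplets), then one update of f_p on the configured objective with f_r's
#' parameters frozen. Each module early-stops independently when its
#' validation loss has not improved by at least `minDelta` for `patience`
#' consecutive epochs; the returned module is its best-validation snapshot.
#'
#' @param treatment a [PerturbationDataset-class] of treatment triplets.
#' @param g the [CausalGraph-class].
#' @param config a [trainConfig()].
#' @param diseaseData optional [PerturbationDataset-class] of disease
#'   triplets, added to f_r's training set when `config$useDiseaseData`.
#' @param trainIdx,valIdx sample indices into `treatment`; if `NULL`, a
#'   seeded 8:2 split of all samples is made.
#' @return list with `fr`, `fp` (trained models), `history` (per-epoch loss
#'   data.frame) and `config`.
#' @export
trainModel <- function(treatment, g, config, diseaseData = NULL,
                       trainIdx = NULL, valIdx = NULL) {
  stopifnot(inherits(config, "TrainConfig"))
  S <- ncol(treatment)
  if (is.null(trainIdx) || is.null(valIdx)) {
    ix <- withSeed(childSeed(config$seed, "holdout"), sample.int(S))
    nVal <- max(1L, floor(0.2 * S))
    valIdx <- ix[seq_len(nVal)]; trainIdx <- ix[-seq_len(nVal)]
  }
  useDisease <- config$useDiseaseData && !is.null(diseaseData)
  exprFit <- cbind(initialState(treatment)[, trainIdx, drop = FALSE],
                   outcomeState(treatment)[, trainIdx, drop = FALSE])
  if (useDisease) exprFit <- cbind(exprFit, initialState(diseaseData))
  thr <- fitBins(exprFit, config$B)
  nodes <- nodeIds(g)
  mkCfg <- function(label) defaultModelConfig(
    config$K, config$d, config$B, config$hidden, config$aggregator,
    childSeed(config$seed, label))
  netFr <- initNet("response", nodes, thr, mkCfg("fr-init"))
  netFp <- initNet("perturbagen", nodes, thr, mkCfg("fp-init"))

  ## Full-batch by default; with batchSize set, samples are partitioned once
  ## (seeded) into chunks and each epoch takes one Adam step per chunk.
  chunks <- if (is.null(config$batchSize)) list(trainIdx)
            else {
              sh <- withSeed(childSeed(config$seed, "batches"),
                             sample(trainIdx))
              unname(split(sh, ceiling(seq_along(sh) / config$batchSize)))
            }
  frBatchChunks <- lapply(seq_along(chunks), function(ci) {
    if (ci == 1L && useDisease)
      buildFrBatch(g, list(treatment, diseaseData),
                   list(chunks[[ci]], seq_len(ncol(diseaseData))),
                   config$aggregator, thr, config$B)
    else
      buildFrBatch(g, list(treatment), list(chunks[[ci]]),
                   config$aggregator, thr, config$B)
  })
  frValBatch <- buildFrBatch(g, list(treatment), list(valIdx),
                             config$aggregator, thr, config$B)
  A0 <- buildAdj(g, config$aggregator)
  fpChunks <- lapply(chunks, function(ix) {
    d <- buildFpData(treatment, ix, thr, config$B)
    d$A <- expandAdj(A0, length(ix))
    d
  })
  fpVal <- buildFpData(treatment, valIdx, thr, config$B)
  fpVal$A <- expandAdj(A0, length(valIdx))

  adamFr <- adamInit(netFr$par); adamFp <- adamInit(netFp$par)
  esFr <- list(best = Inf, bestPar = netFr$par, counter = 0L, active = TRUE)
  esFp <- list(best = Inf, bestPar = netFp$par, counter = 0L, active = TRUE)
  hist <- vector("list", config$maxEpochs)

  for (epoch in seq_len(config$maxEpochs)) {
    lossFr <- NA_real_
    if (esFr$active) {
      acc <- 0
      for (batch in frBatchChunks) {
        st <- frEpoch(netFr, batch)
        acc <- acc + st$loss
        if (!is.finite(st$loss))
          stopf("f_r training diverged (non-finite loss) at epoch %d", epoch)
        upd <- adamStep(netFr$par, st$grads, adamFr, config$learningRate)
        netFr$par <- upd$par; adamFr <- upd$state
      }
      lossFr <- acc / length(frBatchChunks)
    }
    lossFp <- NA_real_
    if (esFp$active) {
      acc <- 0
      for (fpTrain in fpChunks) {
        st <- fpEpoch(netFp, netFr, fpTrain, config$lossMode)
        acc <- acc + st$loss
        if (!is.finite(st$loss))
          stopf("f_p training diverged (non-finite loss) at epoch %d", epoch)
        upd <- adamStep(netFp$par, st$grads, adamFp, config$learningRate)
        netFp$par <- upd$par; adamFp <- upd$state
      }
      lossFp <- acc / length(fpChunks)
    }
    valFr <- frEpoch(netFr, frValBatch, wantGrad = FALSE)$loss
    valFp <- fpEpoch(netFp, netFr, fpVal, config$lossMode,
                     wantGrad = FALSE)$loss
    if (esFr$active)
      esFr <- esUpdate(esFr, valFr, netFr$par, config$minDelta, config$patience)
    if (esFp$active)
      esFp <- esUpdate(esFp, valFp, netFp$par, config$minDelta, config$patience)
    hist[[epoch]] <- data.frame(epoch = epoch, lossFr = lossFr,
                                lossFp = lossFp, valFr = valFr, valFp = valFp,
                                frActive = esFr$active, fpActive = esFp$active)
    if (!esFr$active && !esFp$active) break
  }
  netFr$par <- esFr$bestPar
  netFp$par <- esFp$bestPar
  list(fr = netToModel(netFr), fp = netToModel(netFp),
       history = do.call(rbind, hist[!vapply(hist, is.null, TRUE)]),
       trainIdx = trainIdx, valIdx = valIdx, config = config)
}

#' Grid search over the number of GNN layers
#'
#' Trains one model per depth in `config$KGrid` on the given train/validation
#' indices and selects the depth with the best (highest) validation nDCG of
#' the discovery module; ties go to the smaller depth.
#'
#' @inheritParams trainModel
#' @return the winning [trainModel()] result, augmented with `K` (selected
#'   depth) and `gridNDCG` (named validation nDCG per depth).
#' @export
gridSearchK <- function(treatment, g, config, diseaseData = NULL,
                        trainIdx = NULL, valIdx = NULL) {
  fits <- list(); ndcgs <- numeric(0)
  for (K in config$KGrid) {
    cfgK <- config; cfgK$K <- as.integer(K)
    fit <- trainModel(treatment, g, cfgK, diseaseData, trainIdx, valIdx)
    v <- fit$valIdx
    A0 <- expandAdj(buildAdj(g, cfgK$aggregator), length(v))
    net <- modelToNet(fit$fp)
    sc <- perturbagenForwardMatrix(net, A0,
                                   initialState(treatment)[, v, drop = FALSE],
                                   outcomeState(treatment)[, v, drop = FALSE])$scores
    truths <- interventionSets(treatment)[v]
    nodes <- nodeIds(g)
    vals <- vapply(seq_along(v), function(s) {
      ndcg(rankNodes(setNames(sc[, s], nodes)), truths[[s]], length(nodes))
    }, 0)
    fits[[as.character(K)]] <- fit
    ndcgs[as.character(K)] <- mean(vals)
  }
  best <- names(ndcgs)[which.max(ndcgs)]  # which.max takes the first (smaller K) on ties
  out <- fits[[best]]
  out$K <- as.integer(best)
  out$gridNDCG <- ndcgs
  out
}
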