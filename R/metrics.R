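## Ranking and response-prediction metrics.

truthMembers <- function(truth) {
  if (is(truth, "InterventionSet")) members(truth) else as.character(truth)
}

## Ranks (1-based positions) of the truth nodes in a ranking.
truthRanks <- function(ranking, truth) {
  stopifnot(is(ranking, "PerturbagenRanking"))
  mem <- truthMembers(truth)
  if (length(mem) == 0L) stopf("truth set must be non-empty")
  ids <- rankedNodes(ranking)
  r <- match(mem, ids)
  if (anyNA(r)) stopf("truth node(s) absent from the ranking")
  r
}

#' Normalized discounted cumulative gain for target ranking
#'
#' `DCG = sum over true targets of (1 - rank/n) / log2(rank + 1)` -- the gain
#' of a true target at rank `r` is `1 - r/n`, discounted logarithmically --
#' normalized by the ideal DCG that places all `|truth|` targets at ranks
#' `1..|truth|`. Lies in `[0, 1]` and equals 1 iff all true targets occupy
#' the top ranks.
#'
#' @param ranking a [PerturbagenRanking-class].
#' @param truth the true target set ([InterventionSet-class] or character).
#' @param n total number of nodes (defaults to the ranking's length).
#' @return nDCG in `[0, 1]`.
#' @export
ndcg <- function(ranking, truth, n = length(nodeScores(ranking))) {
  r <- truthRanks(ranking, truth)
  gain <- function(rk) (1 - rk / n) / log2(rk + 1)
  sum(gain(r)) / sum(gain(seq_along(r)))
}

#' Recall among the top-k ranked nodes
#'
#' @inheritParams ndcg
#' @param k prefix size, `1 <= k <= n`.
#' @return `|top-k intersect truth| / |truth|`.
#' @export
recallAtK <- function(ranking, truth, k) {
  stopifnot(k >= 1, k <= length(nodeScores(ranking)))
  r <- truthRanks(ranking, truth)
  sum(r <= k) / length(r)
}

#' Accurately-predicted indicator and percentage
#'
#' A sample is accurately predicted when the top-`N` ranked nodes
#' (`N` = the sample's true target-set size) share at least one gene with the
#' true target set. `pctAccuratelyPredicted` is `100 *` the mean of the
#' indicator over samples.
#'
#' @inheritParams ndcg
#' @return logical (`accuratelyPredicted`) / percentage in `[0, 100]`.
#' @export
accuratelyPredicted <- function(ranking, truth) {
  r <- truthRanks(ranking, truth)
  any(r <= length(r))
}

#' @rdname accuratelyPredicted
#' @param rankings list of [PerturbagenRanking-class].
#' @param truths list of truth sets, aligned with `rankings`.
#' @export
pctAccuratelyPredicted <- function(rankings, truths) {
  100 * mean(mapply(accuratelyPredicted, rankings, truths))
}

#' Sample-wise R-squared of a predicted expression state
#'
#' Square of the Pearson correlation between the predicted and the true
#' state of one sample. Undefined (returned as `NA`) when either vector is
#' constant.
#'
#' @param pred,truth numeric vectors, length >= 3.
#' @return squared Pearson correlation in `[0, 1]`, or `NA`.
#' @export
samplewiseR2 <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 3L)
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0) return(NA_real_)
  stats::cor(pred, truth)^2
}

#' Perturbagen-wise R-squared
#'
#' For a set of predicted and true treated samples sharing one perturbagen,
#' the per-gene means over each set are computed and the squared Pearson
#' correlation of the least-squares regression of mean truth on mean
#' prediction is reported.
#'
#' @param predSet,truthSet genes x samples matrices for one perturbagen.
#' @return squared Pearson correlation, or `NA` for constant means.
#' @export
perturbagenwiseR2 <- function(predSet, truthSet) {
  stopifnot(nrow(predSet) == nrow(truthSet))
  mp <- rowMeans(predSet); mt <- rowMeans(truthSet)
  if (stats::sd(mp) == 0 || stats::sd(mt) == 0) return(NA_real_)
  stats::cor(mp, mt)^2
}

#' Network proximity between predicted and true target sets
#'
#' Mean over all pairs `(p, r)` of the undirected shortest-path distance
#' between the predicted set `P` and the true set `R`:
#' `d(P, R) = (1 / |R||P|) * sum_r sum_p spd(p, r)`. Pairs in different
#' components (infinite distance) are excluded from the average; their count
#' is reported in the `"excluded"` attribute. With `closest = TRUE` a
#' closest-node variant is computed instead: the mean over true targets of
#' the distance to their nearest predicted node (off by default; the
#' all-pairs mean is the primary definition).
#'
#' @param g a [CausalGraph-class].
#' @param predicted,truth non-empty node sets (character vectors or
#'   [InterventionSet-class]).
#' @param closest use the closest-node variant.
#' @return non-negative scalar (NA when every pair is disconnected), with
#'   attribute `"excluded"`.
#' @export
networkProximity <- function(g, predicted, truth, closest = FALSE) {
  P <- truthMembers(predicted); R <- truthMembers(truth)
  if (!length(P) || !length(R)) stopf("sets must be non-empty")
  ip <- match(P, nodeIds(g)); ir <- match(R, nodeIds(g))
  if (anyNA(c(ip, ir))) stopf("set member(s) not in graph")
  D <- spdMatrix(g, ip, ir)
  if (closest) {
    mins <- apply(D, 2L, min)
    fin <- is.finite(mins)
    return(structure(if (any(fin)) mean(mins[fin]) else NA_real_,
                     excluded = sum(!fin)))
  }
  fin <- is.finite(D)
  structure(if (any(fin)) mean(D[fin]) else NA_real_,
            excluded = sum(!fin))
}

#' Per-sample evaluation of trained modules on a test set
#'
#' For every test sample, ranks nodes with the discovery module and computes
#' nDCG, recall at 1/10/100 (capped at `n`), the accurately-predicted
#' indicator and, running the response module under the true intervention,
#' the sample-wise R-squared; perturbagen-wise R-squared is computed per
#' perturbagen group. `reconstructionR2` additionally scores the closed
#' loop: the response module's prediction under the *predicted* top-N target
#' set (N = true set size) against the observed treated state. Forward
#' passes are batched per perturbagen.
#'
#' @param fr,fp trained modules.
#' @param g the [CausalGraph-class].
#' @param dataset a [PerturbationDataset-class] of treatment triplets.
#' @param idx sample indices to evaluate (default all).
#' @return list with `perSample` (data.frame), `perPerturbagen` (data.frame)
#'   and `summary` (named numeric: mean metrics, a [MetricsReport] row).
#' @export
evaluateModels <- function(fr, fp, g, dataset, idx = seq_len(ncol(dataset))) {
  nodes <- nodeIds(g)
  n <- length(nodes)
  netFp <- modelToNet(fp); netFr <- modelToNet(fr)
  A0 <- buildAdj(g, fp@config$aggregator)
  cd <- SummarizedExperiment::colData(dataset)
  init <- initialState(dataset); outc <- outcomeState(dataset)
  targets <- interventionSets(dataset)
  groups <- split(idx, cd$perturbagenId[idx])
  per <- list(); perP <- list()
  for (pid in names(groups)) {
    ix <- groups[[pid]]
    xd <- init[, ix, drop = FALSE]; xt <- outc[, ix, drop = FALSE]
    sc <- perturbagenForwardMatrix(netFp, expandAdj(A0, length(ix)),
                                   xd, xt)$scores
    u <- targets[[ix[1L]]]
    flags <- matrix(0, n, length(ix)); flags[match(u, nodes), ] <- 1
    Au <- expandAdj(buildAdj(mutilate(g, u), fr@config$aggregator),
                    length(ix))
    predT <- responseForwardMatrix(netFr, Au, xd, flags)$pred
    rks <- lapply(seq_len(ncol(sc)), function(s)
      rankNodes(setNames(sc[, s], nodes)))
    predSets <- lapply(seq_along(ix), function(s)
      utils::head(rankedNodes(rks[[s]]), length(targets[[ix[s]]])))
    ## closed-loop reconstruction: f_r under the predicted target set,
    ## batched with one block-diagonal operator over the group's samples
    fpredM <- matrix(0, n, length(ix))
    for (s in seq_along(ix)) fpredM[match(predSets[[s]], nodes), s] <- 1
    Apred <- Matrix::bdiag(lapply(predSets, function(ps)
      buildAdj(mutilate(g, ps), fr@config$aggregator)))
    reconM <- responseForwardMatrix(netFr, methods::as(Apred, "CsparseMatrix"),
                                    xd, fpredM)$pred
    rows <- lapply(seq_along(ix), function(s) {
      rk <- rks[[s]]
      truth <- targets[[ix[s]]]
      predSet <- predSets[[s]]
      recon <- reconM[, s]
      data.frame(sample = ix[s], perturbagen = pid,
                 nTruth = length(truth),
                 ndcg = ndcg(rk, truth, n),
                 recall1 = recallAtK(rk, truth, 1L),
                 recall10 = recallAtK(rk, truth, min(10L, n)),
                 recall100 = recallAtK(rk, truth, min(100L, n)),
                 accurate = accuratelyPredicted(rk, truth),
                 samplewiseR2 = samplewiseR2(predT[, s], xt[, s]),
                 reconstructionR2 = samplewiseR2(recon, xt[, s]),
                 topPredicted = paste(predSet, collapse = ","))
    })
    per[[pid]] <- do.call(rbind, rows)
    perP[[pid]] <- data.frame(perturbagen = pid, nSamples = length(ix),
                              perturbagenwiseR2 = perturbagenwiseR2(predT, xt))
  }
  perSample <- do.call(rbind, unname(per))
  perPerturbagen <- do.call(rbind, unname(perP))
  summary <- c(ndcg = mean(perSample$ndcg),
               recall1 = mean(perSample$recall1),
               recall10 = mean(perSample$recall10),
               recall100 = mean(perSample$recall100),
               pctAccuratelyPredicted = 100 * mean(perSample$accurate),
               samplewiseR2 = mean(perSample$samplewiseR2, na.rm = TRUE),
               reconstructionR2 = mean(perSample$reconstructionR2,
                                       na.rm = TRUE),
               perturbagenwiseR2 = mean(perPerturbagen$perturbagenwiseR2,
                                        na.rm = TRUE))
  list(perSample = perSample, perPerturbagen = perPerturbagen,
       summary = summary)
}
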