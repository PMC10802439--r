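## Cross-validation splits: systematic random folds within a context, and
## leave-cell-out splits across contexts.

#' Random k-fold cross-validation split with 8:2 train/validation
#'
#' Partitions samples into `nFolds` near-equal folds (sizes differ by at most
#' one). For each held-out test fold, the remaining samples are subdivided
#' 8:2 into training and validation sets for early stopping. Seeded and
#' reproducible.
#'
#' @param dataset a [PerturbationDataset-class] (or a sample count).
#' @param nFolds number of folds (default 5).
#' @param seed integer seed.
#' @return a [SampleSplit-class].
#' @export
makeRandomSplits <- function(dataset, nFolds = 5L, seed = 1L) {
  S <- if (is(dataset, "PerturbationDataset")) ncol(dataset)
       else as.integer(dataset)
  if (S < nFolds) stopf("need at least %d samples for %d folds", nFolds, nFolds)
  withSeed(seed, {
    fold <- sample(rep_len(seq_len(nFolds), S))
    assignments <- lapply(seq_len(nFolds), function(f) {
      rest <- which(fold != f)
      nVal <- max(1L, floor(0.2 * length(rest)))
      val <- sample(rest, nVal)
      list(train = setdiff(rest, val), val = val, test = which(fold == f))
    })
    new("SampleSplit", nFolds = as.integer(nFolds), fold = as.integer(fold),
        assignments = assignments, seed = as.integer(seed))
  })
}

#' Leave-cell-out split
#'
#' Trains on random splits of a single context (cell line) and tests on every
#' sample of all other contexts: per fold, train/validation are an 8:2 split
#' of the training context's remaining samples and the test set is the union
#' of all other contexts.
#'
#' @param datasets a named list of [PerturbationDataset-class] objects (one
#'   per context) or a single combined dataset with multiple contexts.
#' @param trainContext name of the context to train on.
#' @param nFolds number of folds within the training context.
#' @param seed integer seed.
#' @return list with `dataset` (the combined [PerturbationDataset-class]) and
#'   `split` (a [SampleSplit-class] indexing into it).
#' @export
makeLeaveCellOut <- function(datasets, trainContext, nFolds = 5L, seed = 1L) {
  combined <- if (is.list(datasets))
    do.call(SummarizedExperiment::cbind, unname(datasets))
  else datasets
  ctx <- sampleContext(combined)
  if (length(unique(ctx)) < 2L)
    stopf("leave-cell-out requires at least two contexts")
  if (!trainContext %in% ctx) stopf("unknown context '%s'", trainContext)
  inTrain <- which(ctx == trainContext)
  testIdx <- which(ctx != trainContext)
  if (length(inTrain) < nFolds)
    stopf("training context has too few samples for %d folds", nFolds)
  withSeed(seed, {
    foldLocal <- sample(rep_len(seq_len(nFolds), length(inTrain)))
    fold <- rep(NA_integer_, ncol(combined))
    fold[inTrain] <- foldLocal
    assignments <- lapply(seq_len(nFolds), function(f) {
      rest <- inTrain[foldLocal != f]
      nVal <- max(1L, floor(0.2 * length(rest)))
      val <- sample(rest, nVal)
      list(train = setdiff(rest, val), val = val, test = testIdx)
    })
    list(dataset = combined,
         split = new("SampleSplit", nFolds = as.integer(nFolds), fold = fold,
                     assignments = assignments, seed = as.integer(seed)))
  })
}

#' @describeIn makeRandomSplits fold assignments accessor
#' @param x a [SampleSplit-class].
#' @param fold fold number.
#' @export
foldIndices <- function(x, fold) {
  stopifnot(is(x, "SampleSplit"), fold >= 1L, fold <= x@nFolds)
  x@assignments[[fold]]
}
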