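test_that("random splits partition samples with near-equal folds and 8:2 train/val", {
  sp <- makeRandomSplits(10, nFolds = 5, seed = 3)
  expect_equal(as.vector(table(sp@fold)), rep(2L, 5))
  for (f in 1:5) {
    a <- foldIndices(sp, f)
    expect_setequal(c(a$train, a$val, a$test), 1:10)
    expect_length(intersect(a$train, a$val), 0)
    expect_equal(a$test, which(sp@fold == f))
    expect_equal(length(a$val), max(1, floor(0.2 * 8)))
  }
  expect_identical(makeRandomSplits(10, 5, seed = 3)@assignments,
                   sp@assignments)
  expect_error(makeRandomSplits(3, 5, seed = 1), "at least")
})

test_that("leave-cell-out tests on entirely unseen contexts", {
  fx <- tinyTreatment(m = 6)
  dsA <- fx$data
  dsB <- generateTreatmentDataset(fx$scm, fx$lib, 4, seed = 20,
                                  diseaseGenes = fx$dg, context = "ctxB")
  SummarizedExperiment::colData(dsA)$context <- "ctxA"
  lco <- makeLeaveCellOut(list(A = dsA, B = dsB), "ctxA", nFolds = 3, seed = 1)
  nA <- ncol(dsA)
  for (f in 1:3) {
    a <- foldIndices(lco$split, f)
    expect_setequal(a$test, nA + seq_len(ncol(dsB)))
    expect_true(all(c(a$train, a$val) <= nA))
  }
  expect_error(makeLeaveCellOut(list(A = dsA), "ctxA"), "two contexts")
  expect_error(makeLeaveCellOut(list(A = dsA, B = dsB), "ctxZ"), "unknown")

  dsC <- generateTreatmentDataset(fx$scm, fx$lib, 3, seed = 30,
                                  diseaseGenes = fx$dg, context = "ctxC")
  lco3 <- makeLeaveCellOut(list(A = dsA, B = dsB, C = dsC), "ctxB",
                           nFolds = 2, seed = 1)
  a <- foldIndices(lco3$split, 1)
  ctx <- sampleContext(lco3$dataset)
  expect_setequal(ctx[a$test], c("ctxA", "ctxC"))
})

test_that("the early-stopping counter resets exactly on minDelta improvements", {
  run <- function(trace, minDelta, patience) {
    es <- list(best = Inf, bestPar = NULL, counter = 0L, active = TRUE)
    stoppedAt <- NA_integer_
    for (i in seq_along(trace)) {
      es <- pd$esUpdate(es, trace[i], i, minDelta, patience)
      if (!es$active) { stoppedAt <- i; break }
    }
    list(stoppedAt = stoppedAt, best = es$best, bestPar = es$bestPar)
  }
  ## improvements of exactly minDelta reset; anything smaller counts down
  tr <- c(1, 0.9, 0.8999, 0.8998, 0.8997)       # minDelta 0.01, patience 3
  r <- run(tr, 0.01, 3)
  expect_equal(r$stoppedAt, 5L)
  expect_equal(r$best, 0.9)
  expect_equal(r$bestPar, 2)                     # snapshot from the best epoch
  ## huge minDelta: stop after exactly patience + 1 evaluations
  r2 <- run(seq(1, 0.1, length.out = 50), 10, 15)
  expect_equal(r2$stoppedAt, 16L)
  ## patience-15 / 1e-5 rule on a synthetic trace: 1e-5 improvements keep it
  ## alive, 9e-6 improvements do not
  alive <- run(1 - cumsum(rep(1e-5, 40)), 1e-5, 15)
  expect_true(is.na(alive$stoppedAt))
  ## improvements too small to ever clear minDelta from the best value
  dead <- run(c(1, rep(1 - 5e-7, 40)), 1e-5, 15)
  expect_equal(dead$stoppedAt, 16L)
})

test_that("training runs deterministically and freezes f_r inside f_p updates", {
  fx <- tinyTreatment(m = 6)
  g <- fx$scm@graph
  cfg <- trainConfig(maxEpochs = 5, d = 3, B = 4, K = 1, seed = 11,
                     KGrid = 1L)
  fit1 <- trainModel(fx$data, g, cfg)
  fit2 <- trainModel(fx$data, g, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$fp@params, fit2$fp@params)

  ## freezing contract: an f_p step leaves f_r's parameters bit-identical
  ## and produces no gradient entries for them
  thr <- fitBins(initialState(fx$data), 4)
  mcfg <- pd$defaultModelConfig(K = 1L, d = 3L, B = 4L, hidden = 6L, seed = 1L)
  netFr <- pd$initNet("response", nodeIds(g), thr, mcfg)
  netFp <- pd$initNet("perturbagen", nodeIds(g), thr, mcfg)
  frSnapshot <- netFr$par
  fpd <- pd$buildFpData(fx$data, 1:8, thr, 4L)
  fpd$A <- pd$expandAdj(pd$buildAdj(g, "mean"), 8L)
  st <- pd$fpEpoch(netFp, netFr, fpd, "supercycle")
  upd <- pd$adamStep(netFp$par, st$grads, pd$adamInit(netFp$par), 0.01)
  expect_identical(netFr$par, frSnapshot)
  expect_false(any(c("flag0", "flag1") %in% names(st$grads)))
  expect_setequal(names(st$grads), names(netFp$par))

  ## huge minDelta: both modules stop after exactly patience + 1 epochs
  cfgStop <- trainConfig(maxEpochs = 50, patience = 3, minDelta = 1e6,
                         d = 3, B = 4, K = 1, seed = 11)
  fitS <- trainModel(fx$data, g, cfgStop)
  expect_equal(nrow(fitS$history), 4L)
  expect_false(fitS$history$frActive[4])
  expect_false(fitS$history$fpActive[4])
})

test_that("supercycle loss decomposes into supervision plus cycle at fixed parameters", {
  fx <- tinyTreatment(m = 4)
  g <- fx$scm@graph
  thr <- fitBins(initialState(fx$data), 4)
  mcfg <- pd$defaultModelConfig(K = 1L, d = 3L, B = 4L, hidden = 6L, seed = 2L)
  netFr <- pd$initNet("response", nodeIds(g), thr, mcfg)
  netFp <- pd$initNet("perturbagen", nodeIds(g), thr, mcfg)
  fpd <- pd$buildFpData(fx$data, 1:8, thr, 4L)
  fpd$A <- pd$expandAdj(pd$buildAdj(g, "mean"), 8L)
  lsc <- pd$fpEpoch(netFp, netFr, fpd, "supercycle", wantGrad = FALSE)
  ls <- pd$fpEpoch(netFp, netFr, fpd, "super", wantGrad = FALSE)
  lc <- pd$fpEpoch(netFp, netFr, fpd, "cycle", wantGrad = FALSE)
  expect_equal(lsc$loss, ls$loss + lc$loss, tolerance = 1e-12)
})

test_that("the depth grid search selects by validation nDCG with ties to smaller K", {
  fx <- tinyTreatment(m = 8)
  g <- fx$scm@graph
  cfg <- trainConfig(maxEpochs = 4, d = 3, B = 4, seed = 5, KGrid = 2L)
  fit <- gridSearchK(fx$data, g, cfg)
  expect_equal(fit$K, 2L)                        # singleton grid
  expect_named(fit$gridNDCG, "2")

  cfg2 <- trainConfig(maxEpochs = 4, d = 3, B = 4, seed = 5, KGrid = c(1L, 2L))
  fit2 <- gridSearchK(fx$data, g, cfg2)
  expect_true(fit2$K %in% c(1L, 2L))
  expect_length(fit2$gridNDCG, 2L)
  expect_equal(fit2$K,
               as.integer(names(fit2$gridNDCG)[which.max(fit2$gridNDCG)]))
})
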