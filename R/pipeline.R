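## End-to-end orchestration: simulate -> train -> evaluate -> benchmark.
## All randomness derives from a single root seed through named child seeds,
## so identical configs yield identical outputs.

#' Default pipeline configuration
#'
#' Returns the nested configuration driving [runSimulate()], [runTrain()],
#' [runEvaluate()] and [runBenchmark()]; [readRunConfig()] merges a YAML file
#' over these defaults. Simulation defaults define the reference study
#' conditions: a 60-gene SCM, 3 disease genes, a 20-perturbagen library of
#' 1-3-gene target sets and 40 treatment samples per perturbagen.
#'
#' @param outDir output directory.
#' @param seed root seed.
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(outDir = "pdisco-run", seed = 1L) {
  list(
    outDir = outDir,
    seed = as.integer(seed),
    simulate = list(nNodes = 60L, arcDensity = 0.08, noiseSd = 0.05,
                    nDiseaseGenes = 3L, nPerturbagens = 20L,
                    perturbagenSizes = c(1L, 3L), mPerPerturbagen = 40L,
                    mDisease = 100L, context = "ctxA"),
    train = list(lossMode = "supercycle", maxEpochs = 25L, patience = 15L,
                 minDelta = 1e-5, learningRate = 0.01, batchSize = 128L,
                 KGrid = c(1L, 2L), useDiseaseData = TRUE, d = 8L, B = 5L,
                 aggregator = "mean", nFolds = 5L, gridSearch = TRUE),
    benchmark = list(kind = "confounder",
                     levels = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                     nGroups = 50L, meanRange = c(-0.5, 0.5),
                     sdRange = c(0.1, 0.5))
  )
}

#' Read a pipeline configuration YAML
#'
#' @param path YAML file; keys override [defaultRunConfig()] entries.
#' @param overrides optional named list of `section$key` overrides.
#' @return nested configuration list.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- defaultRunConfig()
  mergeList <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        mergeList(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  if (!is.null(path)) cfg <- mergeList(cfg, yaml::read_yaml(path))
  mergeList(cfg, overrides)
}

trainConfigFrom <- function(cfg) {
  tc <- cfg$train
  trainConfig(lossMode = tc$lossMode, maxEpochs = tc$maxEpochs,
              patience = tc$patience, minDelta = tc$minDelta,
              learningRate = tc$learningRate, batchSize = tc$batchSize,
              KGrid = tc$KGrid, useDiseaseData = tc$useDiseaseData,
              K = tc$KGrid[1L], d = tc$d, B = tc$B,
              aggregator = tc$aggregator, seed = childSeed(cfg$seed, "train"))
}

#' Simulate the reference study: SCM, graph, disease and treatment datasets
#'
#' Samples a ground-truth SCM, picks disease genes and a perturbagen library
#' of random target sets, generates disease and treatment intervention
#' triplets, and (when `cfg$outDir` is set) writes the proxy causal graph
#' edge list plus both datasets with a provenance manifest.
#'
#' @param cfg configuration from [defaultRunConfig()]/[readRunConfig()].
#' @param write write outputs to `cfg$outDir` (default `TRUE`).
#' @return list with `scm`, `graph`, `diseaseGenes`, `library`, `disease`,
#'   `treatment`.
#' @export
runSimulate <- function(cfg, write = TRUE) {
  sc <- cfg$simulate
  scm <- sampleSCM(sc$nNodes, sc$arcDensity, childSeed(cfg$seed, "scm"),
                   noiseSd = sc$noiseSd)
  g <- scm@graph
  nodes <- nodeIds(g)
  picks <- withSeed(childSeed(cfg$seed, "sets"), {
    dg <- sample(nodes, sc$nDiseaseGenes)
    lib <- list()
    sizes <- sample(seq(sc$perturbagenSizes[1L], sc$perturbagenSizes[2L]),
                    sc$nPerturbagens, replace = TRUE)
    for (i in seq_len(sc$nPerturbagens))
      lib[[sprintf("P%02d", i)]] <- InterventionSet(sample(nodes, sizes[i]))
    list(dg = dg, lib = lib)
  })
  diseaseGenes <- InterventionSet(picks$dg, kind = "disease")
  disease <- generateDiseaseDataset(scm, diseaseGenes, sc$mDisease,
                                    childSeed(cfg$seed, "disease"),
                                    context = sc$context)
  treatment <- generateTreatmentDataset(scm, picks$lib, sc$mPerPerturbagen,
                                        childSeed(cfg$seed, "treatment"),
                                        diseaseGenes, context = sc$context)
  if (write && !is.null(cfg$outDir)) {
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
    writeEdgeList(g, file.path(cfg$outDir, "graph.tsv"))
    prov <- list(seed = cfg$seed, scm_seed = scm@seed,
                 disease_genes = picks$dg)
    writeDataset(disease, file.path(cfg$outDir, "disease"), extra = prov)
    writeDataset(treatment, file.path(cfg$outDir, "treatment"), extra = prov)
  }
  list(scm = scm, graph = g, diseaseGenes = diseaseGenes,
       library = picks$lib, disease = disease, treatment = treatment)
}

#' Train per-fold models with cross-validation
#'
#' Builds the seeded k-fold split and trains (optionally grid-searching the
#' GNN depth) one model pair per fold. Checkpoints and a per-epoch loss TSV
#' are written under `cfg$outDir/models` when requested.
#'
#' @param cfg pipeline configuration.
#' @param sim result of [runSimulate()]; simulated afresh if `NULL`.
#' @param folds folds to train (default all).
#' @param write write checkpoints and logs.
#' @return list with `fits` (per fold), `split`, `sim`.
#' @export
runTrain <- function(cfg, sim = NULL, folds = NULL, write = TRUE) {
  if (is.null(sim)) sim <- runSimulate(cfg, write = write)
  split <- makeRandomSplits(sim$treatment, cfg$train$nFolds,
                            childSeed(cfg$seed, "split"))
  folds <- folds %||% seq_len(cfg$train$nFolds)
  tcfg <- trainConfigFrom(cfg)
  fits <- lapply(folds, function(f) {
    a <- foldIndices(split, f)
    if (isTRUE(cfg$train$gridSearch))
      gridSearchK(sim$treatment, sim$graph, tcfg, sim$disease,
                  a$train, a$val)
    else
      trainModel(sim$treatment, sim$graph, tcfg, sim$disease, a$train, a$val)
  })
  names(fits) <- sprintf("fold%d", folds)
  if (write && !is.null(cfg$outDir)) {
    mdir <- file.path(cfg$outDir, "models")
    dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
    for (f in names(fits)) {
      saveCheckpoint(fits[[f]]$fr, file.path(mdir, paste0(f, "_fr.yaml")))
      saveCheckpoint(fits[[f]]$fp, file.path(mdir, paste0(f, "_fp.yaml")))
      utils::write.table(fits[[f]]$history,
                         file.path(mdir, paste0(f, "_log.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(fits = fits, split = split, sim = sim)
}

#' Evaluate trained models and baselines on held-out folds
#'
#' Computes per-sample metrics on each fold's test set for the trained model
#' and the random baseline, the aggregate comparison with paired one-tailed
#' t-tests, and the network-proximity Mann-Whitney comparison of the model's
#' predicted target sets against random predictions.
#'
#' @param cfg pipeline configuration.
#' @param trained result of [runTrain()]; trained afresh if `NULL`.
#' @param write write TSV/YAML outputs under `cfg$outDir/evaluation`.
#' @return list with `summary` (per fold x method), `aggregate`, `proximity`,
#'   `perSample`.
#' @export
runEvaluate <- function(cfg, trained = NULL, write = TRUE) {
  if (is.null(trained)) trained <- runTrain(cfg, write = write)
  sim <- trained$sim
  nodes <- nodeIds(sim$graph)
  n <- length(nodes)
  ## all-pairs undirected hop distances, computed once for proximity
  Dall <- spdMatrix(sim$graph, seq_len(n), seq_len(n))
  pairProx <- function(P, R) {
    d <- Dall[match(P, nodes), match(R, nodes), drop = FALSE]
    fin <- is.finite(d)
    if (any(fin)) mean(d[fin]) else NA_real_
  }
  rows <- list(); perSample <- list()
  proxModel <- c(); proxRandom <- c()
  for (f in seq_along(trained$fits)) {
    fit <- trained$fits[[f]]
    test <- foldIndices(trained$split, f)$test
    ev <- evaluateModels(fit$fr, fit$fp, sim$graph, sim$treatment, test)
    perSample[[f]] <- cbind(fold = f, ev$perSample)
    truths <- interventionSets(sim$treatment)[test]
    ## random-baseline metrics on the same samples, plus proximity values
    rnd <- lapply(seq_along(test), function(s)
      baselineRank("random", n, nodes = nodes,
                   seed = childSeed(cfg$seed, sprintf("rb-%d-%d", f, s))))
    rndRow <- c(
      ndcg = mean(mapply(function(r, tr) ndcg(r, tr, n), rnd, truths)),
      recall1 = mean(mapply(function(r, tr) recallAtK(r, tr, 1L), rnd, truths)),
      recall10 = mean(mapply(function(r, tr) recallAtK(r, tr, min(10L, n)),
                             rnd, truths)),
      recall100 = mean(mapply(function(r, tr) recallAtK(r, tr, min(100L, n)),
                              rnd, truths)),
      pctAccuratelyPredicted = pctAccuratelyPredicted(rnd, truths))
    rows[[length(rows) + 1L]] <- data.frame(fold = f, method = "model",
                                            t(ev$summary))
    rows[[length(rows) + 1L]] <- data.frame(
      fold = f, method = "random",
      t(c(rndRow, samplewiseR2 = NA_real_, reconstructionR2 = NA_real_,
          perturbagenwiseR2 = NA_real_)))
    ## proximity of predicted vs true target sets, model and random
    ord <- match(test, ev$perSample$sample)
    for (s in seq_along(test)) {
      truth <- truths[[s]]
      top <- strsplit(ev$perSample$topPredicted[ord[s]], ",")[[1L]]
      pm <- pairProx(top, truth)
      pr <- pairProx(utils::head(rankedNodes(rnd[[s]]), length(truth)), truth)
      if (is.finite(pm)) proxModel <- c(proxModel, pm)
      if (is.finite(pr)) proxRandom <- c(proxRandom, pr)
    }
  }
  summary <- do.call(rbind, rows)
  perSample <- do.call(rbind, perSample)
  metricCols <- c("ndcg", "recall1", "recall10", "recall100",
                  "pctAccuratelyPredicted")
  long <- do.call(rbind, lapply(metricCols, function(mc)
    data.frame(method = summary$method, metric = mc, fold = summary$fold,
               value = summary[[mc]] / if (mc == "pctAccuratelyPredicted") 100 else 1)))
  aggregate <- aggregateAndTest(long, focal = "model")
  proximity <- proximityTest(proxModel, proxRandom,
                             seed = childSeed(cfg$seed, "boot"))
  if (write && !is.null(cfg$outDir)) {
    edir <- file.path(cfg$outDir, "evaluation")
    dir.create(edir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(perSample, file.path(edir, "per_sample.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summary, file.path(edir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(list(U = proximity$U, p = proximity$p,
                          rank_biserial = proximity$rankBiserial,
                          ci = as.numeric(proximity$ci)),
                     file.path(edir, "proximity.yaml"))
  }
  list(summary = summary, aggregate = aggregate, proximity = proximity,
       perSample = perSample)
}

#' Robustness sweep over graph/data corruption levels
#'
#' Re-runs train + evaluate at each corruption level of the configured kind:
#' `"confounder"` (latent-confounder noise at the given fraction of gene
#' groups), `"bridge"` / `"random"` (fractions of bridge / random edges
#' removed from the graph), or `"confidence"` (graph filtered at confidence
#' quantiles). Level 0 (or quantile 0) leaves the inputs untouched. One
#' metrics row per level per trained fold.
#'
#' @param cfg pipeline configuration; `cfg$benchmark$kind` and
#'   `cfg$benchmark$levels` define the schedule.
#' @param sim optional pre-computed [runSimulate()] result.
#' @param folds folds to train per level (default fold 1 only, keeping the
#'   sweep linear in the number of levels).
#' @param write write `benchmark.tsv` under `cfg$outDir`.
#' @return data.frame: one row per level x fold x method with mean metrics.
#' @export
runBenchmark <- function(cfg, sim = NULL, folds = 1L, write = TRUE) {
  if (is.null(sim)) sim <- runSimulate(cfg, write = write)
  bk <- cfg$benchmark
  out <- list()
  for (lev in bk$levels) {
    simL <- sim
    lseed <- childSeed(cfg$seed, sprintf("level-%g", lev))
    if (lev > 0) {
      if (bk$kind == "confounder") {
        spec <- confounderSpec(nGroups = bk$nGroups, meanRange = bk$meanRange,
                               sdRange = bk$sdRange, fractionPerturbed = lev,
                               seed = lseed)
        simL$treatment <- injectConfounders(sim$treatment, spec)
        simL$disease <- injectConfounders(sim$disease, spec)
      } else if (bk$kind == "bridge") {
        simL$graph <- removeBridgeEdges(sim$graph, lev, lseed)
      } else if (bk$kind == "random") {
        simL$graph <- removeRandomEdges(sim$graph, lev, lseed)
      } else if (bk$kind == "confidence") {
        simL$graph <- filterByConfidence(sim$graph, lev)
      } else stopf("unknown benchmark kind '%s'", bk$kind)
    }
    trained <- runTrain(cfg, sim = simL, folds = folds, write = FALSE)
    ev <- runEvaluate(cfg, trained, write = FALSE)
    out[[length(out) + 1L]] <- cbind(kind = bk$kind, level = lev,
                                     seed = lseed, ev$summary)
  }
  res <- do.call(rbind, out)
  if (write && !is.null(cfg$outDir)) {
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(res, file.path(cfg$outDir, "benchmark.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
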