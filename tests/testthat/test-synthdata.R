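test_that("sampled SCMs are acyclic DAGs with seeded parameters", {
  s1 <- sampleSCM(10, 0.3, seed = 4)
  s2 <- sampleSCM(10, 0.3, seed = 4)
  expect_identical(s1@weights, s2@weights)
  expect_identical(arcs(s1@graph), arcs(s2@graph))
  expect_true(validObject(s1))

  s0 <- sampleSCM(5, 0, seed = 1)
  expect_equal(nrow(arcs(s0@graph)), 0L)

  ## arc count within binomial bounds of density * C(n, 2)
  s <- sampleSCM(50, 0.1, seed = 7)
  m <- nrow(arcs(s@graph))
  mu <- 0.1 * choose(50, 2); sd <- sqrt(choose(50, 2) * 0.1 * 0.9)
  expect_true(abs(m - mu) < 5 * sd)
  expect_true(all(abs(s@weights) >= 0.5 & abs(s@weights) <= 2))
})

test_that("state simulation follows the logistic structural equations", {
  scm <- sampleSCM(6, 0.4, seed = 2, noiseSd = 0)
  ## zero weights: every free node is logistic(bias)
  scm0 <- scm; scm0@weights[] <- 0
  x <- simulateState(scm0, noiseSeed = 1)
  expect_equal(unname(x), plogis(scm0@biases))

  ## clamped node takes exactly the clamp value
  v <- nodeIds(scm@graph)[3]
  x <- simulateState(scm, u = v, clampValues = setNames(0.9, v), noiseSeed = 1)
  expect_identical(unname(x[v]), 0.9)

  ## hand evaluation on a chain a -> b with w = 2, b_b = -1, a clamped to 1
  g <- CausalGraph(c("a", "b"), cbind(1L, 2L), origin = "directed")
  chain <- new("SCMParams", graph = g, weights = 2, biases = c(0, -1),
               noiseSd = 0, activation = "logistic", topoOrder = 1:2,
               seed = 1L)
  x <- simulateState(chain, u = "a", clampValues = c(a = 1), noiseSeed = 1)
  expect_equal(unname(x["b"]), plogis(2 * 1 - 1))

  expect_error(simulateState(scm, u = v, clampValues = c(zz = 0.5)),
               "clampValues")

  ## with noiseSd = 0 the state is a pure function of (scm, u, clamps)
  x1 <- simulateState(scm, u = v, clampValues = setNames(0.2, v), noiseSeed = 1)
  x2 <- simulateState(scm, u = v, clampValues = setNames(0.2, v), noiseSeed = 99)
  expect_identical(x1, x2)
})

test_that("interventions change only descendants (noise-free)", {
  set.seed(17)
  for (i in 1:15) {
    scm <- sampleSCM(sample(4:12, 1), runif(1, 0.2, 0.5),
                     seed = sample.int(1e6, 1), noiseSd = 0)
    nodes <- nodeIds(scm@graph)
    base <- simulateState(scm, noiseSeed = 1)
    v <- sample(nodes, 1)
    newVal <- clamp01(base[v] + 0.3)
    x <- simulateState(scm, u = v, clampValues = setNames(newVal, v),
                       noiseSeed = 1)
    changed <- which(abs(x - base) > 1e-12)
    allowed <- c(match(v, nodes),
                 oracleDescendants(scm@graph, match(v, nodes)))
    expect_true(all(changed %in% allowed))
  }
})

test_that("disease datasets pair healthy and diseased states as specified", {
  scm <- tinySCM(noiseSd = 0)
  dgenes <- nodeIds(scm@graph)[c(2, 5)]
  dg <- InterventionSet(dgenes, kind = "disease")
  ds <- generateDiseaseDataset(scm, dg, m = 3, seed = 8)
  expect_s4_class(ds, "PerturbationDataset")
  expect_equal(ncol(ds), 3L)
  ## noise-free healthy states are identical across samples
  xh <- initialState(ds)
  expect_true(all(xh == xh[, 1]))
  expect_true(all(sampleKind(ds) == "disease"))
  expect_equal(interventionSets(ds)[[2]], dgenes)

  ## explicit clamp to 0 pins those coordinates of the diseased state
  ds0 <- generateDiseaseDataset(scm, dg, m = 3, seed = 8,
                                clampValues = setNames(c(0, 0), dgenes))
  expect_true(all(outcomeState(ds0)[dgenes, ] == 0))

  ## byte-identical regeneration under a fixed seed
  scmN <- tinySCM(noiseSd = 0.1)
  d1 <- generateDiseaseDataset(scmN, dg, m = 50, seed = 123)
  d2 <- generateDiseaseDataset(scmN, dg, m = 50, seed = 123)
  expect_identical(initialState(d1), initialState(d2))
  expect_identical(outcomeState(d1), outcomeState(d2))
})

test_that("treatment datasets record perturbagens and invert exactly at noise 0", {
  scm <- tinySCM(noiseSd = 0)
  nodes <- nodeIds(scm@graph)
  dgenes <- nodes[c(2, 5)]
  dg <- InterventionSet(dgenes, kind = "disease")

  ## the exact-reversal perturbagen (disease genes clamped to their healthy
  ## values) restores the healthy state to machine precision
  xh <- simulateState(scm, noiseSeed = 1)
  lib <- list(REV = InterventionSet(dgenes))
  tr <- generateTreatmentDataset(scm, lib, 2, seed = 3, diseaseGenes = dg,
                                 clampValues = list(REV = xh[dgenes]))
  expect_equal(unname(outcomeState(tr)[, 1]), unname(xh), tolerance = 1e-14)

  expect_error(generateTreatmentDataset(scm, list(), 2, 1, dg), "non-empty")
  expect_error(generateTreatmentDataset(scm, list(InterventionSet("zz")),
                                        2, 1, dg), "not in graph")

  ## bookkeeping: 10 perturbagens x 5 samples, each sample tagged
  lib10 <- lapply(1:10, function(i) InterventionSet(sample(nodes, 2)))
  names(lib10) <- sprintf("P%d", 1:10)
  tr10 <- generateTreatmentDataset(scm, lib10, 5, seed = 4, diseaseGenes = dg)
  expect_equal(ncol(tr10), 50L)
  cd <- SummarizedExperiment::colData(tr10)
  expect_equal(as.vector(table(cd$perturbagenId)), rep(5L, 10))
  expect_equal(interventionSets(tr10)[[6]], members(lib10$P2))
})

test_that("latent confounders perturb the chosen gene groups and stay in bounds", {
  fx <- tinyTreatment(m = 6)
  ds <- fx$data
  spec <- confounderSpec(nGroups = 4, fractionPerturbed = 0.5, seed = 2)
  out <- injectConfounders(ds, spec)
  expect_equal(dim(out), dim(ds))
  expect_identical(interventionSets(out), interventionSets(ds))
  expect_true(all(initialState(out) >= 0 & initialState(out) <= 1))
  expect_true(all(outcomeState(out) >= 0 & outcomeState(out) <= 1))

  ## fixed mean, ~zero sd: affected genes shift by exactly the mean
  ## (up to clamping); exactly fraction * nGroups contiguous groups selected
  spec2 <- confounderSpec(nGroups = 4, meanRange = c(0.3, 0.3),
                          sdRange = c(0, 0), fractionPerturbed = 0.5,
                          seed = 7)
  out2 <- injectConfounders(ds, spec2)
  delta <- initialState(out2) - initialState(ds)
  shiftedGenes <- which(rowSums(abs(delta)) > 0)
  groups <- sort(rep_len(seq_len(4), nrow(ds)))
  expect_equal(length(unique(groups[shiftedGenes])), 2L)
  expect_true(all(abs(delta[shiftedGenes, ] - 0.3) < 1e-12 |
                    initialState(out2)[shiftedGenes, ] == 1))

  ## degenerate spec: zero mean and sd leaves the data unchanged
  spec0 <- confounderSpec(nGroups = 4, meanRange = c(0, 0), sdRange = c(0, 0),
                          fractionPerturbed = 1, seed = 1)
  expect_equal(initialState(injectConfounders(ds, spec0)), initialState(ds))
})

test_that("datasets round-trip exactly through the TSV directory format", {
  fx <- tinyTreatment(m = 5, scm = tinySCM(noiseSd = 0.08))
  dir <- tempfile("ds")
  writeDataset(fx$data, dir, extra = list(seed = 9))
  back <- readDataset(dir)
  expect_identical(initialState(back), initialState(fx$data))
  expect_identical(outcomeState(back), outcomeState(fx$data))
  expect_identical(interventionSets(back), interventionSets(fx$data))
  expect_identical(as.character(sampleKind(back)),
                   as.character(sampleKind(fx$data)))

  ## missing manifest
  file.remove(file.path(dir, "manifest.yaml"))
  expect_error(readDataset(dir), "manifest")

  ## out-of-range expression value is a validation error
  dir2 <- tempfile("ds")
  writeDataset(fx$data, dir2)
  f <- file.path(dir2, "expression_initial.tsv")
  tab <- readLines(f)
  tab[2] <- sub("\t[0-9.]+$", "\t1.2", tab[2])
  writeLines(tab, f)
  expect_error(readDataset(dir2), "outside")
})
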