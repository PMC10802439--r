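rankingFromOrder <- function(ids, ord) {
  scores <- numeric(length(ids))
  scores[match(ord, ids)] <- seq(length(ids), 1)
  rankNodes(setNames(scores, ids))
}

test_that("nDCG follows the 1 - rank/n gain with logarithmic discount", {
  ids <- sprintf("g%d", 1:5)
  ## all true targets in the top ranks: exactly 1
  rk <- rankingFromOrder(ids, ids)
  expect_equal(ndcg(rk, ids[1:2], 5), 1)
  ## singleton truth at rank 2: gain (1 - 2/5) discounted by log2(3),
  ## normalized by the rank-1 gain (1 - 1/5)
  expect_equal(ndcg(rk, ids[2], 5), ((1 - 2 / 5) / log2(3)) / (1 - 1 / 5))
  ## worked instance: truth at rank 3 of 5 -> DCG 0.2, IDCG 0.8, nDCG 0.25
  expect_equal(ndcg(rk, ids[3], 5), 0.25)
  expect_error(ndcg(rk, character(0), 5), "non-empty")
})

test_that("recall@k and accurately-predicted match their definitions", {
  ids <- sprintf("g%d", 1:20)
  rk <- rankingFromOrder(ids, ids)
  expect_equal(recallAtK(rk, ids[1:3], 3), 1)
  expect_equal(recallAtK(rk, ids, 20), 1)
  ## 4 truths, one inside the top 10
  truth <- ids[c(5, 12, 15, 18)]
  expect_equal(recallAtK(rk, truth, 10), 0.25)
  ## recall@k is non-decreasing in k
  rks <- vapply(1:20, function(k) recallAtK(rk, truth, k), 0)
  expect_true(all(diff(rks) >= 0))

  expect_false(accuratelyPredicted(rk, ids[c(10, 12)]))  # top-2 misses both
  expect_true(accuratelyPredicted(rk, ids[c(2, 12)]))
  ## accurately predicted == (recall@|truth| > 0)
  expect_equal(accuratelyPredicted(rk, truth), recallAtK(rk, truth, 4) > 0)

  rankings <- rep(list(rk), 10)
  truths <- c(rep(list(ids[1]), 3), rep(list(ids[20]), 7))
  expect_equal(pctAccuratelyPredicted(rankings, truths), 30)
})

test_that("R-squared variants match hand computations", {
  x <- c(0.1, 0.4, 0.2, 0.9, 0.5)
  expect_equal(samplewiseR2(x, x), 1)
  expect_equal(samplewiseR2(2 * x - 0.05, x), 1)       # affine invariance
  y <- c(0.2, 0.1, 0.5, 0.8, 0.4)
  expect_equal(samplewiseR2(x, y), oracleR2(x, y))
  expect_true(is.na(samplewiseR2(rep(0.5, 5), y)))

  P <- matrix(c(0.1, 0.2, 0.9, 0.4,
                0.3, 0.1, 0.8, 0.6), 4, 2)
  Tm <- matrix(c(0.2, 0.3, 0.7, 0.5,
                 0.1, 0.4, 0.9, 0.3), 4, 2)
  expect_equal(perturbagenwiseR2(P, P), 1)
  expect_equal(perturbagenwiseR2(P, P[, 2:1]), 1)      # mean invariance
  expect_equal(perturbagenwiseR2(P, Tm), oracleR2(rowMeans(P), rowMeans(Tm)))
})

test_that("network proximity averages pairwise distances, excluding disconnected pairs", {
  g <- pathGraph(3)
  expect_equal(as.numeric(networkProximity(g, "a", "a")), 0)
  expect_equal(as.numeric(networkProximity(g, "a", "c")), 2)
  expect_equal(as.numeric(networkProximity(g, c("a", "b"), "c")), 1.5)
  expect_error(networkProximity(g, character(0), "a"), "non-empty")

  two <- CausalGraph(c("a", "b", "c"), rbind(c("a", "b"), c("b", "a")),
                     origin = "undirected-doubled")
  pr <- networkProximity(two, c("a", "c"), "b")
  expect_equal(as.numeric(pr), 1)
  expect_equal(attr(pr, "excluded"), 1L)

  ## symmetry and monotonicity under densification, against the BFS oracle
  set.seed(41)
  for (i in 1:10) {
    g <- randomUndirectedGraph(sample(5:12, 1), p = 0.3)
    nodes <- nodeIds(g)
    P <- sample(nodes, 2); R <- sample(nodes, 2)
    expect_equal(as.numeric(networkProximity(g, P, R)),
                 oracleProximity(g, P, R))
    expect_equal(as.numeric(networkProximity(g, P, R)),
                 as.numeric(networkProximity(g, R, P)))
    ## add an edge between two non-adjacent nodes: proximity cannot grow
    free <- setdiff(nodes, c(nodes[arcs(g)[arcs(g)[, 1] == 1, 2]], nodes[1]))
    if (length(free)) {
      g2 <- CausalGraph(nodes,
                        rbind(arcs(g), c(1L, match(free[1], nodes)),
                              c(match(free[1], nodes), 1L)),
                        origin = "undirected-doubled")
      p1 <- as.numeric(networkProximity(g, P, R))
      p2 <- as.numeric(networkProximity(g2, P, R))
      if (!is.na(p1) && !is.na(p2) &&
          attr(networkProximity(g, P, R), "excluded") ==
            attr(networkProximity(g2, P, R), "excluded"))
        expect_lte(p2, p1)
    }
  }
})

test_that("evaluateModels reports one row per test sample with bounded metrics", {
  fx <- tinyTreatment(m = 5)
  g <- fx$scm@graph
  cfg <- trainConfig(maxEpochs = 5, d = 3, B = 4, K = 1, seed = 7, KGrid = 1L)
  fit <- trainModel(fx$data, g, cfg)
  ev <- evaluateModels(fit$fr, fit$fp, g, fx$data, idx = 1:10)
  expect_equal(nrow(ev$perSample), 10L)
  expect_true(all(ev$perSample$ndcg >= 0 & ev$perSample$ndcg <= 1))
  expect_true(all(ev$perSample$recall10 >= ev$perSample$recall1))
  expect_true(ev$summary["pctAccuratelyPredicted"] >= 0 &&
                ev$summary["pctAccuratelyPredicted"] <= 100)
  expect_equal(nrow(ev$perPerturbagen), 2L)
})
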