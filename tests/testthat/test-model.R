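test_that("bin thresholds are per-gene quantiles with a degenerate-gene rule", {
  expr <- rbind(g1 = seq(0.1, 1, 0.1), g2 = rep(0.4, 10))
  thr <- fitBins(expr, B = 2)
  expect_equal(unname(thr["g1", 1]), median(expr["g1", ]))
  ## constant gene: all thresholds equal, everything lands in the first bin
  bins <- pd$binIndices(expr, fitBins(expr, 5), 5L)
  expect_true(all(bins["g2", ] == 1L))

  ## B = 5 boundaries at 0.2/0.4/0.6/0.8 quantiles; assignment matches a
  ## brute-force comparison loop
  thr5 <- fitBins(expr, 5)
  expect_equal(unname(thr5["g1", ]),
               unname(quantile(expr["g1", ], c(0.2, 0.4, 0.6, 0.8))))
  for (j in 1:10) {
    brute <- 1 + sum(thr5["g1", ] < expr["g1", j])
    expect_equal(unname(bins["g1", j]), brute)
  }
  expect_error(fitBins(expr, 1), "B must be")

  ## global thresholds replicate one pooled set
  thrG <- fitBins(expr, 3, global = TRUE)
  expect_equal(thrG[1, ], thrG[2, ])
})

test_that("node encoding interpolates flag embeddings and is exact by hand", {
  thr <- matrix(0.5, 2, 1)                      # 2 nodes, B = 2
  enc <- nodeEncoding(thr, d = 1,
                      flag0 = matrix(c(1, 2), 2, 1),
                      flag1 = matrix(c(5, 6), 2, 1),
                      bin = matrix(c(10, 20, 30, 40), 4, 1),
                      pos = matrix(c(7, 8), 2, 1))
  ## node 1: x = 0.3 -> bin 1 (row 1), node 2: x = 0.9 -> bin 2 (row 4)
  m0 <- encodeNodes(c(0.3, 0.9), c(0, 0), enc)
  expect_equal(m0, cbind(c(1, 2), c(10, 40), c(7, 8)))
  m1 <- encodeNodes(c(0.3, 0.9), c(1, 1), enc)
  expect_equal(m1[, 1], c(5, 6))
  mHalf <- encodeNodes(c(0.3, 0.9), c(0.5, 0.5), enc)
  expect_equal(mHalf[, 1], (m0[, 1] + m1[, 1]) / 2)
  expect_error(encodeNodes(c(0.3, 0.9), c(2, 0), enc), "flags")
})

test_that("response forward is deterministic, bounded, and graph-blind at K=0", {
  fx <- tinyTreatment()
  g <- fx$scm@graph
  thr <- fitBins(initialState(fx$data), 4)
  fr <- responseModel(g, thr, K = 1, d = 4, seed = 3)
  x <- initialState(fx$data)[, 1]
  flags <- as.numeric(seq_along(x) == 2)
  y1 <- responseForward(fr, g, x, flags)
  y2 <- responseForward(fr, g, x, flags)
  expect_identical(y1, y2)
  expect_true(all(y1 >= 0 & y1 <= 1))
  expect_equal(length(y1), numNodes(g))

  ## K = 0: head only, output independent of the arc set
  fr0 <- responseModel(g, thr, K = 0, d = 4, seed = 3)
  gEmpty <- CausalGraph(nodeIds(g), NULL, origin = "directed")
  expect_identical(responseForward(fr0, g, x, flags),
                   responseForward(fr0, gEmpty, x, flags))
})

test_that("both modules are permutation-equivariant under node relabeling", {
  fx <- tinyTreatment()
  g <- fx$scm@graph
  n <- numNodes(g)
  thr <- fitBins(cbind(initialState(fx$data), outcomeState(fx$data)), 4)
  xd <- initialState(fx$data)[, 1]; xt <- outcomeState(fx$data)[, 1]
  flags <- as.numeric(seq_len(n) == 3)

  permuteModel <- function(model, perm) {
    enc <- model@encoding
    B <- enc@B
    binPerm <- as.vector(vapply(perm, function(i) (i - 1L) * B + seq_len(B),
                                integer(B)))
    enc@thresholds <- enc@thresholds[perm, , drop = FALSE]
    enc@flag0 <- enc@flag0[perm, , drop = FALSE]
    enc@flag1 <- enc@flag1[perm, , drop = FALSE]
    enc@bin <- enc@bin[binPerm, , drop = FALSE]
    enc@pos <- enc@pos[perm, , drop = FALSE]
    model@encoding <- enc
    model@nodes <- model@nodes[perm]
    if (is(model, "PerturbagenModel"))
      model@params$binT <- model@params$binT[binPerm, , drop = FALSE]
    model
  }
  permuteGraph <- function(g, perm) {
    inv <- integer(n); inv[perm] <- seq_len(n)
    CausalGraph(nodeIds(g)[perm], cbind(inv[arcs(g)[, 1]], inv[arcs(g)[, 2]]),
                origin = graphOrigin(g))
  }

  set.seed(5)
  perm <- sample.int(n)
  gP <- permuteGraph(g, perm)

  fr <- responseModel(g, thr, K = 2, d = 4, seed = 3)
  frP <- permuteModel(fr, perm)
  expect_equal(responseForward(frP, gP, xd[perm], flags[perm]),
               responseForward(fr, g, xd, flags)[perm])

  fp <- perturbagenModel(g, thr, K = 2, d = 4, seed = 4)
  fpP <- permuteModel(fp, perm)
  expect_equal(nodeScores(perturbagenForward(fpP, gP, xd[perm], xt[perm])),
               nodeScores(perturbagenForward(fp, g, xd, xt))[perm])
})

test_that("one message-passing layer has a one-hop receptive field", {
  ## star: center c with leaves l1..l4 (undirected-doubled)
  nodes <- c("c", paste0("l", 1:4))
  arcs <- cbind(rep("c", 4), nodes[-1])
  g <- CausalGraph(nodes, rbind(arcs, arcs[, 2:1]),
                   origin = "undirected-doubled")
  thr <- matrix(0.5, 5, 1)
  fr <- responseModel(g, thr, K = 1, d = 4, seed = 6)
  x <- rep(0.3, 5)
  base <- responseForward(fr, g, x, rep(0, 5))
  ## perturb leaf l1's value across its bin boundary
  x2 <- x; x2[2] <- 0.9
  out <- responseForward(fr, g, x2, rep(0, 5))
  expect_false(out["c"] == base["c"])          # center sees every leaf
  expect_false(out["l1"] == base["l1"])        # own value changed
  expect_equal(out[c("l2", "l3", "l4")], base[c("l2", "l3", "l4")])
})

test_that("a node-symmetric discovery model falls back to the tie rule", {
  nodes <- sprintf("g%d", 1:5)
  g <- CausalGraph(nodes, cbind(nodes[-5], nodes[-1]), origin = "directed")
  thr <- matrix(0.5, 5, 1)
  fp <- perturbagenModel(g, thr, K = 0, d = 2, seed = 1)
  ## make every per-node table identical across nodes
  enc <- fp@encoding
  enc@bin <- enc@bin[rep(1:2, 5), , drop = FALSE]
  enc@pos <- enc@pos[rep(1, 5), , drop = FALSE]
  fp@encoding <- enc
  fp@params$binT <- fp@params$binT[rep(1:2, 5), , drop = FALSE]
  rk <- perturbagenForward(fp, g, rep(0.2, 5), rep(0.2, 5))
  expect_equal(rankedNodes(rk), nodes)          # index tie rule
  expect_equal(length(unique(nodeScores(rk))), 1L)
})

test_that("rankNodes orders scores with deterministic tie handling", {
  rk <- rankNodes(c(0.1, 0.9, 0.5))
  expect_equal(rk@order, c(2L, 3L, 1L))
  expect_equal(rankNodes(rep(1, 4))@order, 1:4)
  s1 <- rankNodes(rep(1, 6), tieRule = "shuffle", seed = 9)
  s2 <- rankNodes(rep(1, 6), tieRule = "shuffle", seed = 9)
  expect_identical(s1@order, s2@order)
  expect_error(rankNodes(c(1, NaN)), "finite")
})

test_that("checkpoints reproduce forward outputs bit-identically", {
  fx <- tinyTreatment()
  g <- fx$scm@graph
  thr <- fitBins(cbind(initialState(fx$data), outcomeState(fx$data)), 4)
  fp <- perturbagenModel(g, thr, K = 1, d = 3, seed = 2)
  f <- tempfile(fileext = ".yaml")
  saveCheckpoint(fp, f)
  fp2 <- loadCheckpoint(f)
  xd <- initialState(fx$data)[, 2]; xt <- outcomeState(fx$data)[, 2]
  expect_identical(nodeScores(perturbagenForward(fp2, g, xd, xt)),
                   nodeScores(perturbagenForward(fp, g, xd, xt)))

  fr <- responseModel(g, thr, K = 2, d = 3, seed = 2)
  saveCheckpoint(fr, f)
  fr2 <- loadCheckpoint(f)
  flags <- as.numeric(seq_len(numNodes(g)) == 1)
  expect_identical(responseForward(fr2, g, xd, flags),
                   responseForward(fr, g, xd, flags))
})
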