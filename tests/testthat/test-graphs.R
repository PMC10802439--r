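test_that("edge lists load with undirected doubling, dedup and node order", {
  f <- edgeListFile(c("source\ttarget", "a\tb", "b\tc"))
  g <- loadEdgeList(f)
  expect_equal(nodeIds(g), c("a", "b", "c"))
  expect_equal(nrow(arcs(g)), 4L)
  expect_equal(graphOrigin(g), "undirected-doubled")

  gd <- loadEdgeList(f, directed = TRUE)
  expect_equal(nrow(arcs(gd)), 2L)
  expect_equal(graphOrigin(gd), "directed")

  fdup <- edgeListFile(c("source\ttarget", "a\tb", "b\tc", "a\tb"))
  expect_equal(arcs(loadEdgeList(fdup)), arcs(g))

  ## comma-separated input is accepted too
  fcsv <- edgeListFile(c("source,target", "a,b", "b,c"))
  expect_equal(arcs(loadEdgeList(fcsv)), arcs(g))
})

test_that("edge-list format errors are caught", {
  f <- edgeListFile(c("source\ttarget\tconf", "a\tb\t0.5"))
  expect_error(loadEdgeList(f, confidenceColumn = "score"), "unknown")
  fbad <- edgeListFile(c("source\ttarget\tconf", "a\tb\t1.5"))
  expect_error(loadEdgeList(fbad, confidenceColumn = "conf"), "\\[0, 1\\]")
  fempty <- edgeListFile(character(0))
  expect_error(loadEdgeList(fempty))
  fnoedge <- edgeListFile("source\ttarget")
  expect_error(loadEdgeList(fnoedge), "no edges")
})

test_that("edge lists round-trip through writeEdgeList", {
  f <- edgeListFile(c("source\ttarget\tconf", "a\tb\t0.25", "b\tc\t1"))
  g <- loadEdgeList(f, confidenceColumn = "conf")
  out <- tempfile(fileext = ".tsv")
  writeEdgeList(g, out)
  g2 <- loadEdgeList(out, confidenceColumn = "confidence")
  expect_equal(arcs(g2), arcs(g))
  expect_equal(arcConfidences(g2), arcConfidences(g))

  ## a mutilated doubled graph is asymmetric: per-arc serialization
  gm <- mutilate(g, "b")
  writeEdgeList(gm, out)
  g3 <- loadEdgeList(out, directed = TRUE, confidenceColumn = "confidence")
  expect_setequal(paste(arcs(g3)[, 1], arcs(g3)[, 2]),
                  paste(match(nodeIds(gm)[arcs(gm)[, 1]], nodeIds(g3)),
                        match(nodeIds(gm)[arcs(gm)[, 2]], nodeIds(g3))))
})

test_that("confidence filtering cuts strictly below the linear quantile", {
  nodes <- letters[1:11]
  arcs <- cbind(nodes[1:10], nodes[2:11])
  g <- CausalGraph(nodes, arcs, confidences = seq(0.1, 1, 0.1))
  expect_equal(nrow(arcs(filterByConfidence(g, 0))), 10L)
  ## type-7 quantile of 0.1..1.0 at q = 0.5 is 0.55: arcs >= 0.55 remain
  g5 <- filterByConfidence(g, 0.5)
  expect_equal(nrow(arcs(g5)), 5L)
  expect_true(all(arcConfidences(g5) >= 0.55))
  ## q = 1 keeps only the maximum-confidence arc(s)
  expect_equal(arcConfidences(filterByConfidence(g, 1)), 1)
  ## node set is never changed
  expect_equal(nodeIds(g5), nodeIds(g))
  expect_error(filterByConfidence(pathGraph(), 0.5), "confidences")
})

test_that("mutilation removes exactly the intervened nodes' incoming arcs", {
  ch <- pathGraph(3, directed = TRUE)           # a -> b -> c
  gm <- mutilate(ch, "b")
  expect_equal(arcs(gm), matrix(c(2L, 3L), 1, dimnames = list(NULL, c("from", "to"))))
  expect_equal(nrow(arcs(mutilate(ch, nodeIds(ch)))), 0L)
  expect_error(mutilate(ch, character(0)), "non-empty")
  expect_error(mutilate(ch, "zz"), "not in graph")

  ## doubled triangle: intervening on a removes its two incoming arcs
  tg <- cycleGraph(3)
  gm <- mutilate(tg, "a")
  expect_equal(nrow(arcs(gm)), 4L)
  expect_false(any(arcs(gm)[, 2] == 1L))

  ## property: non-intervened in-neighborhoods unchanged, original untouched
  set.seed(11)
  for (i in 1:20) {
    g <- randomUndirectedGraph(sample(4:10, 1))
    u <- sample(nodeIds(g), 2)
    gm <- mutilate(g, u)
    ui <- match(u, nodeIds(g))
    expect_true(all(!arcs(gm)[, 2] %in% ui))
    for (v in setdiff(seq_len(numNodes(g)), ui))
      expect_identical(sort(arcs(gm)[arcs(gm)[, 2] == v, 1]),
                       sort(arcs(g)[arcs(g)[, 2] == v, 1]))
  }
})

test_that("bridge detection matches remove-and-count oracle", {
  expect_equal(nrow(findBridges(pathGraph(3))), 2L)
  expect_equal(nrow(findBridges(cycleGraph(3))), 0L)
  b <- findBridges(barbellGraph())
  expect_equal(nrow(b), 1L)
  expect_equal(nodeIds(barbellGraph())[b[1, ]], c("c", "d"))

  set.seed(21)
  for (i in 1:25) {
    g <- randomUndirectedGraph(sample(4:12, 1), p = runif(1, 0.15, 0.5))
    got <- findBridges(g)
    want <- oracleBridges(g)
    expect_setequal(paste(got[, 1], got[, 2]), paste(want[, 1], want[, 2]))
  }
})

test_that("edge removal respects the floor count, seeding and identity at 0", {
  g <- pathGraph(5)                              # 4 undirected edges, all bridges
  expect_identical(arcs(removeBridgeEdges(g, 0, 1)), arcs(g))
  expect_identical(arcs(removeRandomEdges(g, 0, 1)), arcs(g))

  g1 <- removeBridgeEdges(g, 0.5, seed = 7)
  expect_equal(nrow(pd$undirectedEdges(g1)), 2L)   # floor(0.5 * 4)
  expect_identical(arcs(removeBridgeEdges(g, 0.5, seed = 7)), arcs(g1))

  ## a tree is all bridges: fraction 1 leaves no edges
  expect_equal(nrow(arcs(removeBridgeEdges(g, 1, seed = 3))), 0L)

  g2 <- removeRandomEdges(cycleGraph(10), 0.5, seed = 5)
  expect_equal(nrow(pd$undirectedEdges(g2)), 5L)
  expect_identical(arcs(removeRandomEdges(cycleGraph(10), 0.5, seed = 5)),
                   arcs(g2))
  ## both arcs of a doubled edge go together
  expect_equal(nrow(arcs(g2)), 10L)
})

test_that("shortest-path distance is a metric on the undirected view", {
  g <- pathGraph(3)
  expect_equal(shortestPathDistance(g, "a", "a"), 0)
  expect_equal(shortestPathDistance(g, "a", "c"), 2)
  two <- CausalGraph(c("a", "b", "c", "d"),
                     rbind(c("a", "b"), c("b", "a"), c("c", "d"), c("d", "c")),
                     origin = "undirected-doubled")
  expect_equal(shortestPathDistance(two, "a", "c"), Inf)
  expect_error(shortestPathDistance(g, "a", "zz"), "unknown")

  set.seed(31)
  for (i in 1:10) {
    g <- randomUndirectedGraph(sample(4:10, 1))
    v <- sample(nodeIds(g), 3)
    d12 <- shortestPathDistance(g, v[1], v[2])
    expect_equal(d12, shortestPathDistance(g, v[2], v[1]))
    expect_equal(d12, oracleSPD(g, v[1], v[2]))
    d13 <- shortestPathDistance(g, v[1], v[3])
    d23 <- shortestPathDistance(g, v[2], v[3])
    expect_true(d13 <= d12 + d23)
  }
})
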