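## Shared fixtures and independent brute-force oracles. The oracles are
## deliberately naive (enumeration, repeated BFS, comparison loops) and never
## share code with the implementation they check.

pd <- asNamespace("perturbDiscover")

## --- graph fixtures -------------------------------------------------------

pathGraph <- function(k = 3, directed = FALSE) {
  nodes <- letters[seq_len(k)]
  arcs <- cbind(nodes[-k], nodes[-1])
  if (!directed) arcs <- rbind(arcs, arcs[, 2:1])
  CausalGraph(nodes, arcs,
              origin = if (directed) "directed" else "undirected-doubled")
}

cycleGraph <- function(k = 3) {
  nodes <- letters[seq_len(k)]
  arcs <- cbind(nodes, nodes[c(2:k, 1)])
  CausalGraph(nodes, rbind(arcs, arcs[, 2:1]), origin = "undirected-doubled")
}

## two triangles joined by one edge (c-d)
barbellGraph <- function() {
  e <- rbind(c("a","b"), c("b","c"), c("a","c"),
             c("d","e"), c("e","f"), c("d","f"),
             c("c","d"))
  CausalGraph(letters[1:6], rbind(e, e[, 2:1]), origin = "undirected-doubled")
}

## random undirected-doubled graph on <= maxN nodes
randomUndirectedGraph <- function(n, p = 0.3) {
  nodes <- sprintf("n%d", seq_len(n))
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  keep <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
  if (nrow(keep) == 0L) keep <- pairs[1, , drop = FALSE]
  arcs <- cbind(nodes[keep[, 1]], nodes[keep[, 2]])
  CausalGraph(nodes, rbind(arcs, arcs[, 2:1]), origin = "undirected-doubled")
}

## --- graph oracles --------------------------------------------------------

## number of connected components of the undirected view, by label flooding
oracleComponents <- function(g) {
  n <- numNodes(g)
  lab <- seq_len(n)
  a <- arcs(g)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(a))) {
      m <- min(lab[a[r, 1]], lab[a[r, 2]])
      if (lab[a[r, 1]] != m || lab[a[r, 2]] != m) {
        lab[a[r, 1]] <- lab[a[r, 2]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(lab))
}

## bridges by remove-each-edge-and-count-components
oracleBridges <- function(g) {
  ue <- pd$undirectedEdges(g)
  base <- oracleComponents(g)
  out <- matrix(integer(0), ncol = 2)
  for (r in seq_len(nrow(ue))) {
    g2 <- pd$removeUndirectedEdges(g, ue[r, , drop = FALSE])
    if (oracleComponents(g2) > base) out <- rbind(out, ue[r, ])
  }
  out
}

## BFS hop distance on the undirected view
oracleSPD <- function(g, a, b) {
  ia <- match(a, nodeIds(g)); ib <- match(b, nodeIds(g))
  if (ia == ib) return(0)
  adj <- arcs(g)
  nbr <- function(v) unique(c(adj[adj[, 1] %in% v, 2], adj[adj[, 2] %in% v, 1]))
  seen <- ia; frontier <- ia; d <- 0
  while (length(frontier)) {
    d <- d + 1
    frontier <- setdiff(nbr(frontier), seen)
    if (ib %in% frontier) return(d)
    seen <- c(seen, frontier)
  }
  Inf
}

## descendants of node idx by iterated one-step expansion over arcs
oracleDescendants <- function(g, idx) {
  a <- arcs(g)
  out <- integer(0); frontier <- idx
  while (length(frontier)) {
    nxt <- setdiff(unique(a[a[, 1] %in% frontier, 2]), c(out, idx))
    out <- c(out, nxt)
    frontier <- nxt
  }
  sort(out)
}

## --- metric oracles -------------------------------------------------------

## brute-force DCG summation under gain (1 - rank/n) and log2(rank+1) discount
oracleNdcg <- function(orderIds, truth, n) {
  dcg <- 0
  for (t in truth) {
    rk <- which(orderIds == t)
    dcg <- dcg + (1 - rk / n) / log2(rk + 1)
  }
  idcg <- 0
  for (rk in seq_along(truth)) idcg <- idcg + (1 - rk / n) / log2(rk + 1)
  dcg / idcg
}

oracleRecallAtK <- function(orderIds, truth, k) {
  hits <- 0
  for (t in truth) if (which(orderIds == t) <= k) hits <- hits + 1
  hits / length(truth)
}

oracleR2 <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  cov <- sum((x - mx) * (y - my))
  (cov / sqrt(sum((x - mx)^2) * sum((y - my)^2)))^2
}

## all-pairs mean shortest-path distance via repeated BFS
oracleProximity <- function(g, P, R) {
  vals <- c()
  for (p in P) for (r in R) {
    d <- oracleSPD(g, p, r)
    if (is.finite(d)) vals <- c(vals, d)
  }
  if (length(vals)) mean(vals) else NA_real_
}

## rank-biserial by explicit pair counting (sign: positive = method smaller)
oracleRankBiserial <- function(m, r) {
  lt <- 0; gt <- 0
  for (a in m) for (b in r) {
    if (a < b) lt <- lt + 1 else if (a > b) gt <- gt + 1
  }
  (lt - gt) / (length(m) * length(r))
}

## exact one-sided MWU p (method smaller) by enumerating group assignments;
## counts wins of the first group via ranks, independent of the package path
oracleMWUp <- function(m, r) {
  pool <- c(m, r); n1 <- length(m)
  uOf <- function(idx) {
    x <- pool[idx]; y <- pool[-idx]
    sum(vapply(x, function(a) sum(a < y) + 0.5 * sum(a == y), 0))
  }
  uObs <- uOf(seq_len(n1))
  combos <- utils::combn(length(pool), n1)
  mean(apply(combos, 2, uOf) >= uObs - 1e-9)
}

## --- model/data fixtures --------------------------------------------------

tinySCM <- function(n = 8, density = 0.3, seed = 5, noiseSd = 0.05)
  sampleSCM(n, density, seed = seed, noiseSd = noiseSd)

tinyTreatment <- function(scm = tinySCM(), m = 4, seed = 9) {
  nodes <- nodeIds(scm@graph)
  dg <- InterventionSet(nodes[c(2, 5)], kind = "disease")
  lib <- list(P1 = InterventionSet(nodes[1]),
              P2 = InterventionSet(nodes[c(3, 7)]))
  list(scm = scm, dg = dg, lib = lib,
       data = generateTreatmentDataset(scm, lib, m, seed = seed,
                                       diseaseGenes = dg))
}

edgeListFile <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
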