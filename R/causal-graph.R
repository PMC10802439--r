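## Graph data model, edge-list I/O, do-operator mutilation and the
## edge-removal corruption procedures.

#' Construct a CausalGraph
#'
#' @param nodes character vector of node (gene) identifiers.
#' @param arcs two-column matrix of directed arcs, either integer indices into
#'   `nodes` or character identifiers.
#' @param confidences optional numeric per-arc confidences in `[0, 1]`.
#' @param origin `"directed"` or `"undirected-doubled"`.
#' @return a [CausalGraph-class] object.
#' @export
CausalGraph <- function(nodes, arcs, confidences = numeric(0),
                        origin = "directed") {
  nodes <- as.character(nodes)
  if (is.null(arcs) || length(arcs) == 0L) {
    arcs <- matrix(integer(0), ncol = 2L)
  } else {
    arcs <- as.matrix(arcs)
    if (is.character(arcs)) {
      idx <- match(arcs, nodes)
      if (anyNA(idx)) stopf("arc endpoint not in node set: %s",
                            paste(unique(arcs[is.na(idx)]), collapse = ", "))
      arcs <- matrix(idx, ncol = 2L)
    }
    storage.mode(arcs) <- "integer"
  }
  colnames(arcs) <- c("from", "to")
  new("CausalGraph", nodes = nodes, arcs = arcs,
      confidences = as.numeric(confidences), origin = origin)
}

#' Accessors for CausalGraph
#'
#' `nodeIds` returns the gene identifiers; `numNodes` the node count; `arcs`
#' the two-column integer arc matrix; `arcConfidences` the per-arc confidence
#' vector (length zero if absent); `graphOrigin` whether the input network was
#' directed or an undirected network doubled into opposing arcs.
#'
#' @param x a [CausalGraph-class].
#' @name CausalGraph-accessors
#' @aliases nodeIds numNodes arcs arcConfidences graphOrigin
NULL

#' @rdname CausalGraph-accessors
#' @export
setMethod("nodeIds", "CausalGraph", function(x) x@nodes)
#' @rdname CausalGraph-accessors
#' @export
setMethod("numNodes", "CausalGraph", function(x) length(x@nodes))
#' @rdname CausalGraph-accessors
#' @export
setMethod("arcs", "CausalGraph", function(x) x@arcs)
#' @rdname CausalGraph-accessors
#' @export
setMethod("arcConfidences", "CausalGraph", function(x) x@confidences)
#' @rdname CausalGraph-accessors
#' @export
setMethod("graphOrigin", "CausalGraph", function(x) x@origin)

setMethod("show", "CausalGraph", function(object) {
  cat(sprintf("CausalGraph with %d nodes, %d arcs (%s%s)\n",
              numNodes(object), nrow(object@arcs), object@origin,
              if (length(object@confidences)) ", with confidences" else ""))
})

## igraph view; undirected = TRUE collapses doubled arcs into simple edges.
asIgraph <- function(g, undirected = FALSE) {
  ig <- igraph::graph_from_edgelist(
    matrix(g@nodes[g@arcs], ncol = 2L), directed = TRUE)
  ig <- ig + igraph::vertices(setdiff(g@nodes, igraph::V(ig)$name))
  ig <- igraph::permute(ig, match(igraph::V(ig)$name, g@nodes))
  if (undirected)
    ig <- igraph::simplify(igraph::as_undirected(ig, mode = "collapse"))
  ig
}

## Unique unordered node pairs of the undirected view, as an m x 2 integer
## matrix with from < to (self-loops excluded; the loaders never create them).
undirectedEdges <- function(g) {
  a <- g@arcs
  if (!nrow(a)) return(matrix(integer(0), ncol = 2L))
  lo <- pmin(a[, 1L], a[, 2L]); hi <- pmax(a[, 1L], a[, 2L])
  keep <- !duplicated(lo * (numNodes(g) + 1) + hi) & lo != hi
  cbind(lo[keep], hi[keep])
}

## Drop the arcs flagged TRUE, keeping confidences aligned.
dropArcs <- function(g, drop) {
  initialize(g, arcs = g@arcs[!drop, , drop = FALSE],
             confidences = if (length(g@confidences))
               g@confidences[!drop] else numeric(0))
}

#' Read a gene-gene network edge list
#'
#' Reads a tab- or comma-separated file with header columns
#' `source`, `target` and optionally a confidence column. Undirected inputs
#' (PPI-like) are doubled into two opposing arcs per edge; duplicate rows are
#' collapsed; node order is first-appearance order (sources before targets
#' within a row).
#'
#' @param path path to the edge-list file.
#' @param directed logical; `FALSE` (default) doubles each edge.
#' @param confidenceColumn optional name of a column with confidences in
#'   `[0, 1]`.
#' @return a [CausalGraph-class].
#' @export
loadEdgeList <- function(path, directed = FALSE, confidenceColumn = NULL) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stopf("empty edge-list file: %s", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stopf("edge list needs at least two columns")
  if (nrow(df) == 0L) stopf("edge list has no edges")
  if (!is.null(confidenceColumn)) {
    if (!confidenceColumn %in% colnames(df))
      stopf("unknown confidence column '%s'", confidenceColumn)
    conf <- as.numeric(df[[confidenceColumn]])
    if (anyNA(conf) || min(conf) < 0 || max(conf) > 1)
      stopf("confidences must parse to [0, 1]")
  } else conf <- NULL
  src <- as.character(df[[1L]]); dst <- as.character(df[[2L]])
  nodes <- unique(as.vector(rbind(src, dst)))
  from <- match(src, nodes); to <- match(dst, nodes)
  if (!directed) {
    from2 <- c(from, to); to2 <- c(to, from)
    conf <- if (is.null(conf)) NULL else c(conf, conf)
    from <- from2; to <- to2
  }
  key <- from * (length(nodes) + 1) + to
  keep <- !duplicated(key)
  CausalGraph(nodes, cbind(from[keep], to[keep]),
              confidences = if (is.null(conf)) numeric(0) else conf[keep],
              origin = if (directed) "directed" else "undirected-doubled")
}

#' Write a CausalGraph back to an edge-list TSV
#'
#' Serializes to `source<TAB>target[<TAB>confidence]`. Undirected-doubled
#' graphs with a symmetric arc set are written with one row per undirected
#' edge so that `loadEdgeList(path)` round-trips losslessly; a mutilated
#' (asymmetric) doubled graph is written with one row per arc and
#' round-trips through `loadEdgeList(path, directed = TRUE)`.
#'
#' @param g a [CausalGraph-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(g, path) {
  a <- g@arcs
  conf <- g@confidences
  symmetric <- function() {
    key <- a[, 1L] * (numNodes(g) + 1) + a[, 2L]
    rev <- a[, 2L] * (numNodes(g) + 1) + a[, 1L]
    all(rev %in% key)
  }
  if (g@origin == "undirected-doubled" && nrow(a) && symmetric()) {
    lo <- pmin(a[, 1L], a[, 2L]); hi <- pmax(a[, 1L], a[, 2L])
    keep <- !duplicated(lo * (numNodes(g) + 1) + hi)
    a <- cbind(lo[keep], hi[keep])
    if (length(conf)) conf <- conf[keep]
  }
  df <- data.frame(source = g@nodes[a[, 1L]], target = g@nodes[a[, 2L]],
                   stringsAsFactors = FALSE)
  if (length(conf)) df$confidence <- conf
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter arcs by confidence quantile
#'
#' Removes arcs whose confidence is strictly below the `q`-th quantile
#' (linear-interpolation quantile, `stats::quantile` type 7) of the graph's
#' confidence distribution. The node set is unchanged. Used for sensitivity
#' analyses on confidence-scored networks (e.g. STRING-like graphs filtered at
#' quantiles 0.1-0.5).
#'
#' @param g a [CausalGraph-class] with confidences.
#' @param quantile fraction in `[0, 1]`.
#' @return the filtered [CausalGraph-class].
#' @export
filterByConfidence <- function(g, quantile) {
  if (!length(g@confidences))
    stopf("graph has no arc confidences")
  stopifnot(quantile >= 0, quantile <= 1)
  cut <- stats::quantile(g@confidences, quantile, type = 7, names = FALSE)
  dropArcs(g, g@confidences < cut)
}

#' Do-operator edge mutilation
#'
#' Removes every arc pointing INTO an intervened node: under an intervention
#' the node's value is set exogenously, so it loses its parents, while its
#' outgoing arcs are retained so the effects of the intervention propagate
#' downstream. The input graph is not modified.
#'
#' @param g a [CausalGraph-class].
#' @param u an [InterventionSet-class] or character vector of node ids.
#' @return the mutilated [CausalGraph-class].
#' @export
setMethod("mutilate", signature("CausalGraph", "ANY"), function(g, u) {
  mem <- if (is(u, "InterventionSet")) u@members else as.character(u)
  if (length(mem) == 0L) stopf("intervention set must be non-empty")
  idx <- match(mem, g@nodes)
  if (anyNA(idx)) stopf("intervened node(s) not in graph: %s",
                        paste(mem[is.na(idx)], collapse = ", "))
  dropArcs(g, g@arcs[, 2L] %in% idx)
})

#' Find bridge edges
#'
#' Bridge edges are those whose removal disconnects parts of the network.
#' Computed on the undirected view of the graph.
#'
#' @param g a [CausalGraph-class].
#' @return integer matrix (two columns) of undirected bridge edges, endpoints
#'   ordered `from < to`.
#' @export
findBridges <- function(g) {
  ig <- asIgraph(g, undirected = TRUE)
  b <- igraph::bridges(ig)
  if (!length(b)) return(matrix(integer(0), ncol = 2L))
  ends <- igraph::ends(ig, b, names = FALSE)
  cbind(pmin(ends[, 1L], ends[, 2L]), pmax(ends[, 1L], ends[, 2L]))
}

## Remove the given undirected edges (m x 2, lo < hi) from g: both arcs when
## the graph is doubled.
removeUndirectedEdges <- function(g, edges) {
  if (!nrow(edges)) return(g)
  n1 <- numNodes(g) + 1
  keyA <- g@arcs[, 1L] * n1 + g@arcs[, 2L]
  keyB <- g@arcs[, 2L] * n1 + g@arcs[, 1L]
  kill <- edges[, 1L] * n1 + edges[, 2L]
  dropArcs(g, keyA %in% kill | keyB %in% kill)
}

#' Corrupt a graph by removing bridge or random edges
#'
#' Emulates incomplete networks by deleting a seeded uniform random subset of
#' `floor(fraction * #edges)` undirected edges -- either among bridge edges
#' only (`removeBridgeEdges`, disconnecting parts of the network) or among all
#' edges (`removeRandomEdges`). Both arcs of a doubled edge are deleted.
#' Deterministic for a fixed seed.
#'
#' @param g a [CausalGraph-class].
#' @param fraction fraction in `[0, 1]` of the candidate edge set to remove.
#' @param seed integer seed.
#' @return the corrupted [CausalGraph-class].
#' @export
removeBridgeEdges <- function(g, fraction, seed) {
  stopifnot(fraction >= 0, fraction <= 1)
  cand <- findBridges(g)
  k <- floor(fraction * nrow(cand))
  if (k == 0L) return(g)
  pick <- withSeed(seed, sample.int(nrow(cand), k))
  removeUndirectedEdges(g, cand[pick, , drop = FALSE])
}

#' @rdname removeBridgeEdges
#' @export
removeRandomEdges <- function(g, fraction, seed) {
  stopifnot(fraction >= 0, fraction <= 1)
  cand <- undirectedEdges(g)
  k <- floor(fraction * nrow(cand))
  if (k == 0L) return(g)
  pick <- withSeed(seed, sample.int(nrow(cand), k))
  removeUndirectedEdges(g, cand[pick, , drop = FALSE])
}

#' Shortest-path (hop) distance on the undirected view
#'
#' @param g a [CausalGraph-class].
#' @param a,b node identifiers.
#' @return non-negative integer hop count, `0` iff `a == b`, `Inf` when the
#'   nodes are in different components.
#' @export
shortestPathDistance <- function(g, a, b) {
  ia <- match(a, g@nodes); ib <- match(b, g@nodes)
  if (anyNA(c(ia, ib))) stopf("unknown node(s): %s",
                              paste(setdiff(c(a, b), g@nodes), collapse = ", "))
  ig <- asIgraph(g, undirected = TRUE)
  as.vector(igraph::distances(ig, v = ia, to = ib))
}

## All-pairs undirected hop distances between two index sets (matrix).
spdMatrix <- function(g, from, to) {
  ig <- asIgraph(g, undirected = TRUE)
  igraph::distances(ig, v = from, to = to)
}

## Descendants (by index) of a node in the directed graph, excluding itself.
descendantsOf <- function(g, idx) {
  ig <- asIgraph(g, undirected = FALSE)
  r <- igraph::subcomponent(ig, idx, mode = "out")
  setdiff(as.integer(r), idx)
}
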