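#' CausalGraph: a proxy causal gene-gene network
#'
#' Directed graph over named gene nodes used as an imperfect stand-in for the
#' true causal graph among genes. Undirected input networks (PPI-like) are
#' doubled into two opposing arcs per edge at load time so that do-operator
#' edge mutilation is well defined; directed inputs (GRN-like) are kept as-is.
#'
#' @slot nodes character vector of gene identifiers, in first-appearance order.
#' @slot arcs integer matrix with two columns (`from`, `to`), rows are directed
#'   arcs indexing into `nodes`. No duplicate arcs.
#' @slot confidences numeric vector of per-arc confidences in `[0, 1]`
#'   (length zero when the input had none).
#' @slot origin either `"directed"` or `"undirected-doubled"`.
#'
#' @seealso [loadEdgeList()], [mutilate()], [findBridges()]
#' @exportClass CausalGraph
setClass("CausalGraph",
  representation(nodes = "character", arcs = "matrix",
                 confidences = "numeric", origin = "character"))

setValidity("CausalGraph", function(object) {
  msg <- NULL
  n <- length(object@nodes)
  if (n == 0L) msg <- c(msg, "graph must have at least one node")
  if (anyDuplicated(object@nodes))
    msg <- c(msg, "duplicate node identifiers")
  a <- object@arcs
  if (!is.integer(a) || ncol(a) != 2L)
    msg <- c(msg, "arcs must be a two-column integer matrix")
  else {
    if (nrow(a) && (min(a) < 1L || max(a) > n))
      msg <- c(msg, "arc endpoint outside node set")
    if (anyDuplicated(a[, 1L] * (n + 1) + a[, 2L]))
      msg <- c(msg, "duplicate arcs")
  }
  if (length(object@confidences) &&
      length(object@confidences) != nrow(a))
    msg <- c(msg, "confidences must match the number of arcs")
  if (length(object@confidences) &&
      (min(object@confidences) < 0 || max(object@confidences) > 1))
    msg <- c(msg, "confidences must lie in [0, 1]")
  if (!object@origin %in% c("directed", "undirected-doubled"))
    msg <- c(msg, "origin must be 'directed' or 'undirected-doubled'")
  if (is.null(msg)) TRUE else msg
})

#' InterventionSet: the genes targeted by a perturbation
#'
#' A non-empty set of gene identifiers perturbed together, either the
#' disease-causing gene set or a perturbagen (single-gene knockout or
#' multi-gene chemical compound target set).
#'
#' @slot members character vector of gene identifiers (unique, non-empty).
#' @slot kind `"disease"` or `"perturbagen"`.
#' @exportClass InterventionSet
setClass("InterventionSet",
  representation(members = "character", kind = "character"))

setValidity("InterventionSet", function(object) {
  msg <- NULL
  if (length(object@members) == 0L)
    msg <- c(msg, "intervention set must be non-empty")
  if (anyDuplicated(object@members))
    msg <- c(msg, "duplicate members")
  if (!object@kind %in% c("disease", "perturbagen"))
    msg <- c(msg, "kind must be 'disease' or 'perturbagen'")
  if (is.null(msg)) TRUE else msg
})

#' SCMParams: ground-truth structural causal model of gene expression
#'
#' A logistic-linear structural causal model over an acyclic [CausalGraph]:
#' each non-intervened gene takes value
#' `logistic(sum_j w_ij x_j + b_i + eps_i)` over its parents `j`, with
#' `eps_i ~ Normal(0, noiseSd)` exogenous noise, evaluated in topological
#' order. States therefore always lie in `[0, 1]`, matching normalized
#' expression. This is the simulator's ground truth from which disease and
#' treatment intervention triplets are drawn.
#'
#' @slot graph acyclic [CausalGraph].
#' @slot weights numeric arc weights, one per arc of `graph`.
#' @slot biases numeric per-node biases.
#' @slot noiseSd non-negative exogenous noise standard deviation.
#' @slot activation currently `"logistic"`.
#' @slot topoOrder integer permutation of nodes, a topological order.
#' @slot seed integer seed used when sampling the model.
#' @exportClass SCMParams
setClass("SCMParams",
  representation(graph = "CausalGraph", weights = "numeric",
                 biases = "numeric", noiseSd = "numeric",
                 activation = "character", topoOrder = "integer",
                 seed = "integer"))

setValidity("SCMParams", function(object) {
  msg <- NULL
  n <- length(object@graph@nodes)
  if (length(object@weights) != nrow(object@graph@arcs))
    msg <- c(msg, "one weight per arc required")
  if (length(object@biases) != n)
    msg <- c(msg, "one bias per node required")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@activation != "logistic")
    msg <- c(msg, "only logistic activation is supported")
  if (length(object@topoOrder) != n || anyDuplicated(object@topoOrder))
    msg <- c(msg, "topoOrder must be a permutation of nodes")
  else {
    pos <- integer(n); pos[object@topoOrder] <- seq_len(n)
    a <- object@graph@arcs
    if (nrow(a) && any(pos[a[, 1L]] >= pos[a[, 2L]]))
      msg <- c(msg, "topoOrder is not a valid topological order (graph must be acyclic)")
  }
  if (is.null(msg)) TRUE else msg
})

#' PerturbationDataset: paired intervention expression states
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding intervention
#' triplets: the `initial` and `outcome` assays are genes x samples matrices
#' in `[0, 1]` (healthy/diseased for disease triplets, diseased/treated for
#' treatment triplets), and `colData` records per sample the intervention
#' `kind`, the `context` (cell-line-like label) and the comma-joined perturbed
#' gene set `targets`.
#'
#' @exportClass PerturbationDataset
setClass("PerturbationDataset", contains = "SummarizedExperiment")

setValidity("PerturbationDataset", function(object) {
  msg <- NULL
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("initial", "outcome") %in% an))
    return("assays 'initial' and 'outcome' are required")
  for (a in c("initial", "outcome")) {
    m <- SummarizedExperiment::assay(object, a)
    if (length(m) && (min(m) < 0 || max(m) > 1))
      msg <- c(msg, sprintf("assay '%s' must lie in [0, 1]", a))
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("kind", "context", "targets")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, "colData must have columns kind, context, targets")
  else if (nrow(cd) && any(!nzchar(cd$targets)))
    msg <- c(msg, "every sample needs a non-empty intervention set")
  if (is.null(msg)) TRUE else msg
})

#' NodeEncoding: learnable per-node feature encoding
#'
#' Encodes each node's scalar inputs into a `3d`-dimensional vector by
#' concatenating (i) a perturbation-flag embedding (interpolation between a
#' per-node "unperturbed" and "perturbed" row for soft flags in `[0, 1]`),
#' (ii) a bin embedding of the expression value, binned by per-gene quantile
#' thresholds into one of `B` bins, and (iii) a per-node positional embedding.
#' All tables are per-node (different between nodes, shared across samples).
#'
#' @slot thresholds genes x (B-1) matrix of non-decreasing per-gene bin
#'   thresholds (quantiles of training expression).
#' @slot B integer bin count (>= 2).
#' @slot d integer embedding dimension.
#' @slot flag0,flag1 n x d matrices: flag-off / flag-on embeddings.
#' @slot bin (n*B) x d matrix; row `(i-1)*B + b` embeds bin `b` of node `i`.
#' @slot pos n x d positional embedding matrix.
#' @exportClass NodeEncoding
setClass("NodeEncoding",
  representation(thresholds = "matrix", B = "integer", d = "integer",
                 flag0 = "matrix", flag1 = "matrix", bin = "matrix",
                 pos = "matrix"))

setValidity("NodeEncoding", function(object) {
  msg <- NULL
  n <- nrow(object@pos); d <- object@d; B <- object@B
  if (B < 2L) msg <- c(msg, "B must be >= 2")
  if (ncol(object@thresholds) != B - 1L)
    msg <- c(msg, "thresholds must have B-1 columns")
  if (nrow(object@thresholds) != n)
    msg <- c(msg, "thresholds must have one row per node")
  if (nrow(object@thresholds) &&
      any(apply(object@thresholds, 1L, is.unsorted)))
    msg <- c(msg, "per-gene thresholds must be non-decreasing")
  dims <- c(ncol(object@flag0), ncol(object@flag1), ncol(object@bin),
            ncol(object@pos))
  if (any(dims != d)) msg <- c(msg, "embedding tables must have d columns")
  if (nrow(object@flag0) != n || nrow(object@flag1) != n ||
      nrow(object@bin) != n * B)
    msg <- c(msg, "embedding table row counts inconsistent with n and B")
  if (is.null(msg)) TRUE else msg
})

#' GNN module classes
#'
#' `ResponseModel` (f_r) maps an initial expression state plus per-node
#' perturbation flags to the predicted post-perturbation state in `[0, 1]^n`,
#' message-passing on the graph mutilated by the intervention. It is a stack
#' of K GNN layers over encoded node features followed by a two-layer
#' feedforward head with a logistic output per node.
#'
#' `PerturbagenModel` (f_p) maps a (diseased, treated) state pair to an
#' unbounded real score per node; the top-ranked nodes are the predicted
#' perturbagen. Same architecture, with the flag embedding replaced by a
#' second expression-bin embedding and a linear (unsquashed) head output.
#'
#' @slot nodes character vector of gene identifiers the model is bound to.
#' @slot encoding [NodeEncoding].
#' @slot params list of weight matrices (GNN layers and head).
#' @slot config list of architecture hyperparameters (K, d, B, hidden, seed).
#' @name gnn-classes
#' @aliases ResponseModel-class PerturbagenModel-class
#' @exportClass ResponseModel
setClass("ResponseModel",
  representation(nodes = "character", encoding = "NodeEncoding",
                 params = "list", config = "list"))

#' @rdname gnn-classes
#' @exportClass PerturbagenModel
setClass("PerturbagenModel",
  representation(nodes = "character", encoding = "NodeEncoding",
                 params = "list", config = "list"))

#' PerturbagenRanking: per-node scores and a tie-broken total order
#'
#' @slot scores numeric vector of per-node scores (finite), named by node.
#' @slot order integer permutation: `order[1]` is the top-ranked node index.
#' @slot tieRule `"index"` (ascending node index, default) or `"shuffle"`
#'   (seeded random tie-break).
#' @exportClass PerturbagenRanking
setClass("PerturbagenRanking",
  representation(scores = "numeric", order = "integer", tieRule = "character"))

setValidity("PerturbagenRanking", function(object) {
  msg <- NULL
  n <- length(object@scores)
  if (any(!is.finite(object@scores))) msg <- c(msg, "scores must be finite")
  if (length(object@order) != n || anyDuplicated(object@order))
    msg <- c(msg, "order must be a permutation of nodes")
  else if (is.unsorted(-object@scores[object@order]))
    msg <- c(msg, "order must sort scores non-increasingly")
  if (is.null(msg)) TRUE else msg
})

#' SampleSplit: cross-validation fold assignments
#'
#' Per-sample fold ids (1..nFolds) with, for each held-out test fold, an 8:2
#' train/validation subdivision of the remaining samples. For leave-cell-out
#' splits the test set is every sample of the held-out contexts and folds are
#' formed within the training context only.
#'
#' @slot nFolds integer number of folds.
#' @slot fold integer per-sample fold id (NA for samples only ever in test,
#'   as in leave-cell-out).
#' @slot assignments list with one element per fold: `list(train=, val=,
#'   test=)` integer sample indices.
#' @slot seed integer seed.
#' @exportClass SampleSplit
setClass("SampleSplit",
  representation(nFolds = "integer", fold = "integer",
                 assignments = "list", seed = "integer"))

setValidity("SampleSplit", function(object) {
  msg <- NULL
  for (a in object@assignments) {
    if (!all(c("train", "val", "test") %in% names(a)))
      msg <- c(msg, "each assignment needs train/val/test")
    else if (length(intersect(a$train, a$val)) ||
             length(intersect(a$train, a$test)) ||
             length(intersect(a$val, a$test)))
      msg <- c(msg, "train/val/test must be disjoint")
  }
  if (is.null(msg)) TRUE else msg
})
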