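## User-facing model objects and forward passes for the two GNN modules.

## Assemble an S4 model from an internal flat net (and back). The encoding
## slot carries the embedding tables; remaining parameters live in @params.
## For PerturbagenModel the flag tables are unused placeholders and @params
## additionally holds the treated-state bin table `binT`.
netToModel <- function(net) {
  cfg <- net$config
  n <- length(net$nodes); d <- cfg$d
  p <- net$par
  if (net$kind == "response") {
    enc <- new("NodeEncoding", thresholds = net$thr, B = cfg$B, d = d,
               flag0 = p$flag0, flag1 = p$flag1, bin = p$bin, pos = p$pos)
    rest <- p[setdiff(names(p), c("flag0", "flag1", "bin", "pos"))]
    new("ResponseModel", nodes = net$nodes, encoding = enc, params = rest,
        config = cfg)
  } else {
    enc <- new("NodeEncoding", thresholds = net$thr, B = cfg$B, d = d,
               flag0 = matrix(0, n, d), flag1 = matrix(0, n, d),
               bin = p$bin, pos = p$pos)
    rest <- p[setdiff(names(p), c("bin", "pos"))]
    new("PerturbagenModel", nodes = net$nodes, encoding = enc, params = rest,
        config = cfg)
  }
}

modelToNet <- function(model) {
  enc <- model@encoding
  if (is(model, "ResponseModel")) {
    par <- c(list(flag0 = enc@flag0, flag1 = enc@flag1, bin = enc@bin,
                  pos = enc@pos), model@params)
    kind <- "response"
  } else {
    par <- c(list(bin = enc@bin, pos = enc@pos), model@params)
    kind <- "perturbagen"
  }
  list(kind = kind, nodes = model@nodes, thr = enc@thresholds,
       config = model@config, par = par)
}

#' Construct an untrained response-prediction module (f_r)
#'
#' f_r maps an initial expression state plus per-node perturbation flags to
#' the predicted post-perturbation state, message-passing on the graph
#' mutilated by the intervention. See [ResponseModel-class].
#'
#' @param g a [CausalGraph-class] the model is bound to.
#' @param thresholds per-gene bin thresholds from [fitBins()].
#' @param K number of GNN layers (>= 0; with `K = 0` the head alone is used
#'   and the output is independent of the graph).
#' @param d embedding dimension.
#' @param hidden head hidden width (default `2 * d`).
#' @param aggregator `"mean"` (default) or `"sum"` neighborhood aggregation.
#' @param seed initialization seed.
#' @return a [ResponseModel-class] / [PerturbagenModel-class].
#' @export
responseModel <- function(g, thresholds, K = 1L, d = 16L, hidden = 2L * d,
                          aggregator = "mean", seed = 1L) {
  cfg <- defaultModelConfig(K, d, ncol(thresholds) + 1L, hidden, aggregator,
                            seed)
  netToModel(initNet("response", nodeIds(g), thresholds, cfg))
}

#' @rdname responseModel
#' @export
perturbagenModel <- function(g, thresholds, K = 1L, d = 16L, hidden = 2L * d,
                             aggregator = "mean", seed = 1L) {
  cfg <- defaultModelConfig(K, d, ncol(thresholds) + 1L, hidden, aggregator,
                            seed)
  netToModel(initNet("perturbagen", nodeIds(g), thresholds, cfg))
}

setMethod("show", "ResponseModel", function(object) {
  cat(sprintf("ResponseModel (f_r): %d nodes, K=%d, d=%d, B=%d, %s aggregation\n",
              length(object@nodes), object@config$K, object@config$d,
              object@config$B, object@config$aggregator))
})

setMethod("show", "PerturbagenModel", function(object) {
  cat(sprintf("PerturbagenModel (f_p): %d nodes, K=%d, d=%d, B=%d, %s aggregation\n",
              length(object@nodes), object@config$K, object@config$d,
              object@config$B, object@config$aggregator))
})

checkModelGraph <- function(model, g) {
  if (!identical(model@nodes, nodeIds(g)))
    stopf("model and graph node sets disagree")
}

## Internal matrix-batch forwards. A must be the sample-level operator
## (expandAdj of the per-sample adjacency; n x n when S = 1).
responseForwardMatrix <- function(net, A, x, flags) {
  enc <- encodeResponseFeatures(net, x, flags)
  fw <- netForward(net, A, enc$H0)
  pred <- matrix(logistic(fw$out), nrow(x), ncol(x))
  list(pred = pred, enc = enc, fw = fw)
}

perturbagenForwardMatrix <- function(net, A, xd, xt) {
  enc <- encodePerturbagenFeatures(net, xd, xt)
  fw <- netForward(net, A, enc$H0)
  scores <- matrix(fw$out, nrow(xd), ncol(xd))
  list(scores = scores, enc = enc, fw = fw)
}

#' Response-module forward pass
#'
#' Predicts the post-perturbation expression state. With hard (0/1) flags the
#' message passing runs on the graph mutilated by the flagged nodes
#' (do-operator); with soft flags (used during cycle training, where
#' gradients must flow through the discovery module's scores) the intact
#' graph is used and the flag embedding is interpolated.
#'
#' @param fr a [ResponseModel-class].
#' @param g the [CausalGraph-class] (same node set as the model).
#' @param x initial expression state in `[0, 1]^n`.
#' @param uFlags per-node perturbation flags in `[0, 1]`.
#' @return named numeric vector in `[0, 1]^n`.
#' @export
responseForward <- function(fr, g, x, uFlags) {
  checkModelGraph(fr, g)
  n <- length(fr@nodes)
  if (length(x) != n || length(uFlags) != n) stopf("state/flag length mismatch")
  if (min(uFlags) < 0 || max(uFlags) > 1) stopf("flags must lie in [0, 1]")
  hard <- all(uFlags %in% c(0, 1))
  gU <- if (hard && any(uFlags == 1)) mutilate(g, fr@nodes[uFlags == 1]) else g
  A <- buildAdj(gU, fr@config$aggregator)
  net <- modelToNet(fr)
  out <- responseForwardMatrix(net, A, matrix(x, ncol = 1L),
                               matrix(uFlags, ncol = 1L))$pred[, 1L]
  setNames(out, fr@nodes)
}

#' Perturbagen-discovery forward pass
#'
#' Scores every node for membership in the perturbagen that shifts the
#' diseased state `xd` to the treated state `xt`, and returns the tie-broken
#' ranking. The discovery module runs on the unmutilated graph (the true
#' intervention set is unknown at inference time).
#'
#' @param fp a [PerturbagenModel-class].
#' @param g the [CausalGraph-class].
#' @param xd,xt diseased / treated expression states in `[0, 1]^n`.
#' @param tieRule `"index"` (default) or `"shuffle"`.
#' @param seed seed for the `"shuffle"` tie rule.
#' @return a [PerturbagenRanking-class].
#' @export
perturbagenForward <- function(fp, g, xd, xt, tieRule = "index", seed = 1L) {
  checkModelGraph(fp, g)
  A <- buildAdj(g, fp@config$aggregator)
  net <- modelToNet(fp)
  sc <- perturbagenForwardMatrix(net, A, matrix(xd, ncol = 1L),
                                 matrix(xt, ncol = 1L))$scores[, 1L]
  rankNodes(setNames(sc, fp@nodes), tieRule = tieRule, seed = seed)
}

#' Rank nodes by score
#'
#' Produces the total order over nodes sorting scores non-increasingly; ties
#' are broken by ascending node index (default, deterministic) or by a seeded
#' shuffle.
#'
#' @param scores finite numeric vector (optionally named by node).
#' @param tieRule `"index"` or `"shuffle"`.
#' @param seed seed used by the `"shuffle"` rule.
#' @return a [PerturbagenRanking-class].
#' @export
rankNodes <- function(scores, tieRule = c("index", "shuffle"), seed = 1L) {
  tieRule <- match.arg(tieRule)
  if (any(is.na(scores)) || any(!is.finite(scores)))
    stopf("scores must be finite and non-missing")
  ord <- if (tieRule == "index") order(-scores, seq_along(scores))
         else withSeed(seed, order(-scores, sample.int(length(scores))))
  new("PerturbagenRanking", scores = as.numeric(scores) |>
        setNames(names(scores)), order = as.integer(ord), tieRule = tieRule)
}

#' Accessors for PerturbagenRanking
#'
#' `rankedNodes` returns node names (or indices when unnamed) from best to
#' worst; `nodeScores` the raw per-node scores.
#'
#' @param x a [PerturbagenRanking-class].
#' @name PerturbagenRanking-accessors
#' @aliases rankedNodes nodeScores
NULL

#' @rdname PerturbagenRanking-accessors
#' @export
setMethod("rankedNodes", "PerturbagenRanking", function(x) {
  if (is.null(names(x@scores))) x@order else names(x@scores)[x@order]
})

#' @rdname PerturbagenRanking-accessors
#' @export
setMethod("nodeScores", "PerturbagenRanking", function(x) x@scores)

setMethod("show", "PerturbagenRanking", function(object) {
  top <- utils::head(rankedNodes(object), 5L)
  cat(sprintf("PerturbagenRanking over %d nodes (tie rule: %s); top: %s\n",
              length(object@scores), object@tieRule,
              paste(top, collapse = " > ")))
})

#' Save / load a model checkpoint
#'
#' Checkpoints are plain-text YAML carrying the architecture config, the node
#' set, thresholds and all parameter matrices at full precision; loading
#' reproduces forward outputs bit-identically on the same platform.
#'
#' @param model a [ResponseModel-class] or [PerturbagenModel-class].
#' @param path output file.
#' @return `path` (save) / the model (load).
#' @export
saveCheckpoint <- function(model, path) {
  net <- modelToNet(model)
  ser <- list(kind = net$kind, nodes = net$nodes,
              thr = list(dim = dim(net$thr),
                         data = sprintf("%.17g", net$thr)),
              config = net$config,
              par = lapply(net$par, function(p) {
                list(dim = dim(p) %||% length(p),
                     data = sprintf("%.17g", p))
              }))
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ser <- yaml::read_yaml(path)
  deser <- function(x) {
    v <- as.numeric(x$data)
    if (length(x$dim) == 2L) matrix(v, x$dim[1L], x$dim[2L]) else v
  }
  thr <- deser(ser$thr)
  par <- lapply(ser$par, deser)
  par$c2 <- as.numeric(par$c2)
  cfg <- ser$config
  cfg$K <- as.integer(cfg$K); cfg$d <- as.integer(cfg$d)
  cfg$B <- as.integer(cfg$B); cfg$hidden <- as.integer(cfg$hidden)
  cfg$seed <- as.integer(cfg$seed)
  netToModel(list(kind = ser$kind, nodes = as.character(ser$nodes), thr = thr,
                  config = cfg, par = par))
}
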