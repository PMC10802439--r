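## Structural-causal-model simulator: ground-truth generative model for
## disease and treatment intervention triplets.

#' Sample a random ground-truth structural causal model
#'
#' Draws a random DAG by fixing a node order and keeping each forward arc
#' independently with probability `arcDensity`, then samples structural
#' parameters: arc weights uniform on `[-2, -0.5] U [0.5, 2]` (magnitude
#' uniform in `[0.5, 2]`, random sign) and node biases uniform in `[-1, 1]`.
#' Deterministic per seed.
#'
#' @param nNodes number of genes (>= 2).
#' @param arcDensity probability of each forward arc.
#' @param seed integer seed.
#' @param noiseSd exogenous noise standard deviation (default 0.05).
#' @return an [SCMParams-class].
#' @export
sampleSCM <- function(nNodes, arcDensity, seed, noiseSd = 0.05) {
  stopifnot(nNodes >= 2, arcDensity >= 0, arcDensity <= 1, noiseSd >= 0)
  withSeed(seed, {
    ord <- sample.int(nNodes)            # topological order of node indices
    pairs <- which(upper.tri(matrix(0, nNodes, nNodes)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < arcDensity
    from <- ord[pairs[keep, 1L]]; to <- ord[pairs[keep, 2L]]
    m <- length(from)
    w <- stats::runif(m, 0.5, 2) * sample(c(-1, 1), m, replace = TRUE)
    b <- stats::runif(nNodes, -1, 1)
    g <- CausalGraph(sprintf("g%d", seq_len(nNodes)), cbind(from, to),
                     origin = "directed")
    new("SCMParams", graph = g, weights = w, biases = b,
        noiseSd = noiseSd, activation = "logistic",
        topoOrder = as.integer(ord), seed = as.integer(seed))
  })
}

setMethod("show", "SCMParams", function(object) {
  cat(sprintf("SCMParams: %d genes, %d arcs, noiseSd = %g\n",
              numNodes(object@graph), nrow(object@graph@arcs), object@noiseSd))
})

## Per-node parent index/weight lists, cached per call site.
scmParents <- function(scm) {
  a <- scm@graph@arcs
  n <- numNodes(scm@graph)
  pa <- vector("list", n); pw <- vector("list", n)
  if (nrow(a)) {
    sp <- split(seq_len(nrow(a)), a[, 2L])
    for (nm in names(sp)) {
      i <- as.integer(nm)
      pa[[i]] <- a[sp[[nm]], 1L]
      pw[[i]] <- scm@weights[sp[[nm]]]
    }
  }
  list(pa = pa, pw = pw)
}

## Vectorized simulation: n x S state matrix. uIdx: intervened node indices;
## clampMat: |u| x S clamp values; eps: n x S exogenous draws (already scaled).
simulateMatrix <- function(scm, uIdx, clampMat, eps) {
  n <- numNodes(scm@graph)
  S <- ncol(eps)
  par <- scmParents(scm)
  x <- matrix(0, n, S)
  inU <- logical(n); inU[uIdx] <- TRUE
  if (length(uIdx)) x[uIdx, ] <- clampMat
  for (i in scm@topoOrder) {
    if (inU[i]) next
    z <- scm@biases[i] + eps[i, ]
    if (length(par$pa[[i]]))
      z <- z + as.vector(crossprod(x[par$pa[[i]], , drop = FALSE],
                                   par$pw[[i]]))
    x[i, ] <- logistic(z)
  }
  rownames(x) <- nodeIds(scm@graph)
  x
}

## Draw the exogenous noise matrix for S samples from a seed.
drawNoise <- function(scm, S, seed) {
  n <- numNodes(scm@graph)
  if (scm@noiseSd == 0) return(matrix(0, n, S))
  withSeed(seed, matrix(stats::rnorm(n * S, 0, scm@noiseSd), n, S))
}

#' Simulate one expression state from the SCM
#'
#' Nodes in the intervention set `u` are clamped to `clampValues`; every other
#' node `i` takes `logistic(sum_j w_ij x_j + b_i + eps_i)` over its parents in
#' the graph mutilated by `u`, evaluated in topological order, with
#' `eps_i ~ Normal(0, noiseSd)`. With `noiseSd = 0` the result is a pure
#' function of the model, the intervention and the clamps.
#'
#' @param scm an [SCMParams-class].
#' @param u optional [InterventionSet-class] (or character vector); `NULL` for
#'   the unperturbed system.
#' @param clampValues named numeric vector in `[0, 1]`, one value per member
#'   of `u`.
#' @param noiseSeed integer seed for the exogenous noise draw.
#' @return named numeric state vector in `[0, 1]^n`.
#' @export
simulateState <- function(scm, u = NULL, clampValues = NULL, noiseSeed = 1L) {
  nodes <- nodeIds(scm@graph)
  if (is.null(u)) {
    uIdx <- integer(0); clampMat <- matrix(0, 0, 1)
  } else {
    mem <- if (is(u, "InterventionSet")) members(u) else as.character(u)
    uIdx <- match(mem, nodes)
    if (anyNA(uIdx)) stopf("intervened node(s) not in graph")
    if (is.null(clampValues) || !all(mem %in% names(clampValues)))
      stopf("clampValues must provide a value for every intervened node")
    cv <- as.numeric(clampValues[mem])
    if (min(cv) < 0 || max(cv) > 1) stopf("clamp values must lie in [0, 1]")
    clampMat <- matrix(cv, length(uIdx), 1)
  }
  eps <- drawNoise(scm, 1L, noiseSeed)
  simulateMatrix(scm, uIdx, clampMat, eps)[, 1L]
}
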