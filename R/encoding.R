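## Node-feature encoding: quantile bins plus learnable per-node embeddings.

#' Fit per-gene expression bin thresholds
#'
#' Computes, for each gene, the `B - 1` equally spaced quantiles of its
#' training expression values (linear-interpolation quantiles). A value `x`
#' is later assigned to bin `1 + #\{thresholds < x\}`, so constant genes (all
#' thresholds equal to the constant) map every value to the first bin.
#'
#' @param expressionMatrix genes x samples matrix with values in `[0, 1]`.
#' @param B number of bins (>= 2).
#' @param global if `TRUE`, fit one global threshold set on the pooled values
#'   and replicate it across genes (per-gene is the default).
#' @return genes x (B-1) matrix of non-decreasing thresholds.
#' @export
fitBins <- function(expressionMatrix, B, global = FALSE) {
  if (B < 2L) stopf("B must be >= 2")
  probs <- seq_len(B - 1L) / B
  if (global) {
    q <- stats::quantile(expressionMatrix, probs, type = 7, names = FALSE)
    thr <- matrix(q, nrow(expressionMatrix), B - 1L, byrow = TRUE)
  } else {
    thr <- t(apply(expressionMatrix, 1L, stats::quantile, probs = probs,
                   type = 7, names = FALSE))
    if (B == 2L) thr <- matrix(thr, ncol = 1L)
  }
  rownames(thr) <- rownames(expressionMatrix)
  thr
}

#' Construct a NodeEncoding
#'
#' Builds the per-node learnable tables: flag-off/on embeddings, `B` bin
#' embeddings per node, and a positional embedding, all `d`-dimensional and
#' initialized from `Normal(0, 1/sqrt(d))` under `seed`. Tables may also be
#' supplied explicitly (e.g. for hand-computed checks).
#'
#' @param thresholds genes x (B-1) threshold matrix from [fitBins()].
#' @param d embedding dimension.
#' @param seed integer seed for the random initialization.
#' @param flag0,flag1,bin,pos optional explicit tables (see
#'   [NodeEncoding-class] for shapes).
#' @return a [NodeEncoding-class].
#' @export
nodeEncoding <- function(thresholds, d, seed = 1L, flag0 = NULL, flag1 = NULL,
                         bin = NULL, pos = NULL) {
  n <- nrow(thresholds); B <- ncol(thresholds) + 1L
  esd <- 1 / sqrt(d)
  tabs <- withSeed(seed, list(
    flag0 = flag0 %||% matrix(stats::rnorm(n * d, 0, esd), n, d),
    flag1 = flag1 %||% matrix(stats::rnorm(n * d, 0, esd), n, d),
    bin = bin %||% matrix(stats::rnorm(n * B * d, 0, esd), n * B, d),
    pos = pos %||% matrix(stats::rnorm(n * d, 0, esd), n, d)))
  new("NodeEncoding", thresholds = thresholds, B = as.integer(B),
      d = as.integer(d), flag0 = tabs$flag0, flag1 = tabs$flag1,
      bin = tabs$bin, pos = tabs$pos)
}

#' Encode node states and perturbation flags into feature rows
#'
#' Row `i` of the result is the concatenation of (i) the flag embedding,
#' interpolated for soft flags as `(1-f) * E0_i + f * E1_i`, (ii) the bin
#' embedding of `x_i` under node `i`'s thresholds, and (iii) node `i`'s
#' positional embedding.
#'
#' @param x expression state vector in `[0, 1]^n`.
#' @param flags per-node perturbation flags in `[0, 1]` (hard 0/1 or soft).
#' @param enc a [NodeEncoding-class].
#' @return an n x 3d numeric matrix.
#' @export
encodeNodes <- function(x, flags, enc) {
  n <- nrow(enc@pos)
  if (length(x) != n || length(flags) != n)
    stopf("x and flags must have one entry per node (%d)", n)
  if (min(flags) < 0 || max(flags) > 1) stopf("flags must lie in [0, 1]")
  B <- enc@B
  bins <- as.vector(binIndices(matrix(x, ncol = 1L), enc@thresholds, B))
  cbind((1 - flags) * enc@flag0 + flags * enc@flag1,
        enc@bin[(seq_len(n) - 1L) * B + bins, , drop = FALSE],
        enc@pos)
}
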