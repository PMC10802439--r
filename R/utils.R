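## Internal helpers shared across modules.

#' @import methods
#' @useDynLib perturbDiscover, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile rnorm runif rbeta setNames
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData
#' @importFrom S4Vectors DataFrame
NULL

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG state is untouched. All user-facing randomness funnels through this.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             sample.kind = "Rejection")
  }
  force(expr)
}

## Deterministic child seeds from a root seed, so that independent random
## procedures (graph sampling, noise, splits, init) never share a stream.
childSeed <- function(seed, label) {
  stopifnot(is.character(label), length(label) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

## attribute-preserving clamp (pmin/pmax keep the first argument's shape)
clamp01 <- function(x) pmin(pmax(x, 0), 1)

logistic <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
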