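## Baseline rankings and the indirect (response-ranking) wrapper used to
## compare against methods that rank drugs rather than genes.

#' Baseline node rankings
#'
#' `kind = "random"` returns a seeded uniform random permutation of all
#' nodes. `kind = "prior_list"` places the prior genes (e.g. cancer genes,
#' cancer drug targets, or all perturbed genes seen in training) at the top
#' ranks in their given order and shuffles the remaining genes below them.
#' Scores are assigned so that the ranking's score order matches (n down
#' to 1).
#'
#' @param kind `"random"` or `"prior_list"`.
#' @param n number of nodes.
#' @param prior ordered character vector of prior genes (subset of `nodes`);
#'   ignored for `"random"`. An empty prior reduces to the random baseline.
#' @param nodes node identifiers (default `g1..gn` style indices as names are
#'   optional).
#' @param seed integer seed.
#' @return a [PerturbagenRanking-class].
#' @export
baselineRank <- function(kind = c("random", "prior_list"), n,
                         prior = character(0), nodes = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  stopifnot(length(nodes) == n)
  if (kind == "prior_list" && length(prior)) {
    if (anyDuplicated(prior)) stopf("duplicate prior genes")
    pi <- match(prior, nodes)
    if (anyNA(pi)) stopf("prior gene(s) not among nodes")
    rest <- setdiff(seq_len(n), pi)
    ord <- c(pi, withSeed(seed, sample(rest)))
  } else {
    ord <- withSeed(seed, sample.int(n))
  }
  scores <- numeric(n)
  scores[ord] <- seq(n, 1)
  rankNodes(setNames(scores, nodes))
}

#' Indirect gene ranking from per-drug response scores
#'
#' Converts a drug-level ranking into a complete gene-level ranking, the way
#' response-prediction methods without native target ranking are evaluated:
#' drugs are sorted by descending R-squared (ties broken by lexicographic
#' drug id), each drug is expanded to its target genes in seeded random
#' internal order keeping first occurrences, and all genes absent from every
#' ranked drug are appended in seeded shuffled order.
#'
#' @param r2PerPerturbagen named numeric vector: R-squared per drug.
#' @param drugTargets named list: target gene set per drug.
#' @param nodes character vector of all gene identifiers.
#' @param seed integer seed.
#' @return a [PerturbagenRanking-class] over `nodes`.
#' @export
indirectRank <- function(r2PerPerturbagen, drugTargets, nodes, seed = 1L) {
  drugs <- names(r2PerPerturbagen)
  if (!all(drugs %in% names(drugTargets)))
    stopf("drugTargets must cover every ranked drug")
  ordDrugs <- drugs[order(-r2PerPerturbagen, drugs)]
  withSeed(seed, {
    genes <- character(0)
    for (dg in ordDrugs) {
      tg <- as.character(drugTargets[[dg]])
      if (length(tg) > 1L) tg <- sample(tg)
      genes <- c(genes, setdiff(tg, genes))
    }
    genes <- intersect(genes, nodes)
    missing <- setdiff(nodes, genes)
    if (length(missing) > 1L) missing <- sample(missing)
    full <- c(genes, missing)
    scores <- numeric(length(nodes))
    scores[match(full, nodes)] <- seq(length(nodes), 1)
    rankNodes(setNames(scores, nodes))
  })
}
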