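## Statistical comparisons: Mann-Whitney U with rank-biserial effect size and
## bootstrap CI for network proximity, and the aggregate ranking with paired
## t-tests across folds.

## U counts pairs where the method value is SMALLER than the random value
## (ties count 0.5): closer-than-chance proximity means large U. The
## rank-biserial correlation r = 2U/(n1*n2) - 1 is then positive when the
## method is closer than random, equal to
## (#pairs m < r - #pairs m > r) / (n1*n2).
uStatistic <- function(method, random) {
  D <- outer(method, random, "-")
  sum(D < 0) + 0.5 * sum(D == 0)
}

## One-sided p for alternative "method stochastically smaller": P(U >= U_obs).
## Exact permutation enumeration when feasible, otherwise normal
## approximation with tie correction and continuity correction.
mwuPValue <- function(method, random, exactLimit = 20000) {
  n1 <- length(method); n2 <- length(random)
  uObs <- uStatistic(method, random)
  if (choose(n1 + n2, n1) <= exactLimit) {
    pool <- c(method, random)
    idx <- utils::combn(n1 + n2, n1)
    us <- apply(idx, 2L, function(i) uStatistic(pool[i], pool[-i]))
    p <- mean(us >= uObs - 1e-9)
  } else {
    N <- n1 + n2
    ties <- table(c(method, random))
    tieAdj <- sum(ties^3 - ties) / (N * (N - 1))
    mu <- n1 * n2 / 2
    sd <- sqrt(n1 * n2 / 12 * ((N + 1) - tieAdj))
    p <- stats::pnorm((uObs - 0.5 - mu) / sd, lower.tail = FALSE)
  }
  min(max(p, .Machine$double.xmin), 1)
}

#' Mann-Whitney U comparison of proximity distributions
#'
#' Compares per-sample network-proximity values of a method against a random
#' reference with a one-sided Mann-Whitney U test (alternative: the method's
#' distances are smaller than random), the rank-biserial correlation
#' `r = 2U/(n1*n2) - 1` as effect size (positive = method closer than
#' random; `U` counts pairs where the method value is smaller, ties 0.5),
#' and a percentile bootstrap 95% confidence interval of `r`.
#'
#' @param valuesMethod,valuesRandom numeric vectors of proximity values.
#' @param nBoot bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return list with `U`, `p` (one-sided), `rankBiserial`, `ci` (length-2),
#'   `n1`, `n2`.
#' @export
proximityTest <- function(valuesMethod, valuesRandom, nBoot = 1000L,
                          seed = 1L) {
  stopifnot(length(valuesMethod) >= 1L, length(valuesRandom) >= 1L)
  n1 <- length(valuesMethod); n2 <- length(valuesRandom)
  U <- uStatistic(valuesMethod, valuesRandom)
  r <- 2 * U / (n1 * n2) - 1
  p <- mwuPValue(valuesMethod, valuesRandom)
  ci <- withSeed(seed, {
    rs <- vapply(seq_len(nBoot), function(b) {
      m <- sample(valuesMethod, n1, replace = TRUE)
      rr <- sample(valuesRandom, n2, replace = TRUE)
      2 * uStatistic(m, rr) / (n1 * n2) - 1
    }, 0)
    unname(stats::quantile(rs, c(0.025, 0.975), type = 7))
  })
  list(U = U, p = p, rankBiserial = r, ci = ci, n1 = n1, n2 = n2)
}

#' Aggregate metrics across folds and test methods pairwise
#'
#' Computes, per method, the aggregated score (mean of all metric values
#' over metrics and folds) and paired t-tests of the focal method against
#' every competitor, pairing on folds (each fold's value is its mean over
#' metrics). Benchmarking uses a one-tailed test (focal greater); ablation
#' comparisons use the two-tailed variant.
#'
#' @param values data.frame with columns `method`, `metric`, `fold`, `value`.
#' @param focal name of the focal method.
#' @param alternative `"greater"` (one-tailed, default) or `"two.sided"`.
#' @return list with `table` (method, aggregated score, ordered best first)
#'   and `tests` (competitor, t, p).
#' @export
aggregateAndTest <- function(values, focal,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  need <- c("method", "metric", "fold", "value")
  if (!all(need %in% colnames(values))) stopf("values needs columns %s",
                                              paste(need, collapse = ", "))
  folds <- sort(unique(values$fold))
  byMethod <- split(values, values$method)
  for (m in names(byMethod))
    if (!identical(sort(unique(byMethod[[m]]$fold)), folds))
      stopf("misaligned folds for method '%s'", m)
  agg <- vapply(byMethod, function(d) mean(d$value), 0)
  tab <- data.frame(method = names(agg), aggregated = unname(agg))
  tab <- tab[order(-tab$aggregated), ]
  if (!focal %in% names(byMethod)) stopf("unknown focal method '%s'", focal)
  perFold <- function(d) vapply(split(d$value, d$fold), mean, 0)[as.character(folds)]
  fv <- perFold(byMethod[[focal]])
  tests <- lapply(setdiff(names(byMethod), focal), function(m) {
    mv <- perFold(byMethod[[m]])
    sdv <- stats::sd(fv - mv)
    if (is.na(sdv)) {
      ## a single fold cannot support a paired t-test
      data.frame(competitor = m, t = NA_real_, p = NA_real_)
    } else if (sdv == 0) {
      ## degenerate paired differences: identical methods give p = 1; a
      ## constant non-zero difference is the zero-variance limit of the
      ## paired t (|t| -> Inf), reported as the smallest positive double
      d <- mean(fv - mv)
      p <- if (d == 0) 1
           else if (alternative == "two.sided" || d > 0) .Machine$double.xmin
           else 1
      data.frame(competitor = m, t = if (d == 0) NA_real_ else sign(d) * Inf,
                 p = p)
    } else {
      tt <- stats::t.test(fv, mv, paired = TRUE, alternative = alternative)
      data.frame(competitor = m, t = unname(tt$statistic), p = tt$p.value)
    }
  })
  list(table = tab, tests = do.call(rbind, tests))
}
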