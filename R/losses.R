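## Training objectives: continuous-target cross-entropy for the response
## module, and the supervision + cycle-consistency objective for the
## discovery module.

CLIP_EPS <- 1e-12

#' Response-prediction loss (continuous-target cross-entropy)
#'
#' Mean over nodes (and samples) of
#' `-(t * log(p) + (1 - t) * log(1 - p))` with targets `t` in `[0, 1]`
#' (natural log; predictions clipped away from 0/1). For continuous targets
#' the minimum over `p` is attained at `p = t` with value equal to the
#' binary entropy of `t`, not 0.
#'
#' @param pred,target numeric vectors or matrices in `[0, 1]`, same shape.
#' @return non-negative scalar.
#' @export
lossResponse <- function(pred, target) {
  if (length(pred) != length(target)) stopf("pred/target length mismatch")
  if (min(target) < 0 || max(target) > 1) stopf("targets must lie in [0, 1]")
  p <- pmin(1 - CLIP_EPS, pmax(CLIP_EPS, pred))
  mean(-(target * log(p) + (1 - target) * log(1 - p)))
}

## Weighted binary CE of per-node scores against the intervention indicator;
## positives are up-weighted by n/|U| to counter the severe class imbalance.
supervisionLoss <- function(scores, yInd, posWeight) {
  p <- logistic(scores)
  p <- pmin(1 - CLIP_EPS, pmax(CLIP_EPS, p))
  w <- ifelse(yInd == 1, posWeight, 1)
  mean(-w * (yInd * log(p) + (1 - yInd) * log(1 - p)))
}

#' Perturbagen-discovery loss
#'
#' Combines, per `mode`:
#' * `"super"` -- supervision: weighted binary cross-entropy of the logistic
#'   of the per-node scores against the indicator of the true intervention
#'   set, with positive-class weight `n / |U'|`;
#' * `"cycle"` -- cycle consistency: the response loss between the true
#'   treated state and the frozen response module's prediction under the
#'   discovered soft perturbation flags `sigmoid(scores)` (gradients flow
#'   through the flags only, never into f_r);
#' * `"supercycle"` -- their unweighted sum.
#'
#' @param scores per-node scores from the discovery module (vector, or the
#'   [PerturbagenRanking-class] holding them).
#' @param fr the frozen [ResponseModel-class], or a plain function
#'   `f(x, flags) -> prediction` (useful for stubs/diagnostics).
#' @param g the [CausalGraph-class] (ignored when `fr` is a function).
#' @param xd,xt diseased / treated states.
#' @param uTrue the true [InterventionSet-class] (or character vector).
#' @param mode `"supercycle"` (default), `"super"` or `"cycle"`.
#' @return scalar loss with attributes `"supervision"` and `"cycle"` holding
#'   the individual terms.
#' @export
lossPerturbagen <- function(scores, fr, g, xd, xt, uTrue,
                            mode = c("supercycle", "super", "cycle")) {
  mode <- match.arg(mode)
  if (is(scores, "PerturbagenRanking")) scores <- nodeScores(scores)
  n <- length(scores)
  mem <- if (is(uTrue, "InterventionSet")) members(uTrue)
         else as.character(uTrue)
  if (length(mem) == 0L) stopf("true intervention set must be non-empty")
  yInd <- as.numeric(names(scores) %in% mem)
  if (is.null(names(scores))) yInd <- as.numeric(seq_len(n) %in% mem)
  sup <- supervisionLoss(scores, yInd, n / length(mem))
  cyc <- NA_real_
  if (mode != "super") {
    flags <- logistic(scores)
    pred <- if (is.function(fr)) fr(xd, flags)
            else responseForward(fr, g, xd, flags)
    cyc <- lossResponse(pred, xt)
  }
  total <- switch(mode, super = sup, cycle = cyc, supercycle = sup + cyc)
  structure(total, supervision = sup, cycle = cyc)
}
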