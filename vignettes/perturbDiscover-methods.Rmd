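---
title: "Methods: combinatorial perturbagen discovery on proxy causal gene networks"
author: "perturbDiscover maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combinatorial perturbagen discovery on proxy causal gene networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(perturbDiscover)
```

## The problem

Given a diseased cell state we want the *set* of genes that, if perturbed
together, would shift the transcriptional state back toward a desired
(healthy or treated) state. Framed causally: cells follow a structural
causal model (SCM) over genes; a perturbagen is a do-intervention on its
target genes, which severs their incoming regulatory influences (edge
mutilation) while their outgoing influences keep propagating. The true
causal graph is unknown, so a gene–gene network — a protein–protein
interaction network or an inferred regulatory network — serves as a *proxy
causal graph*. Searching all target combinations through a response
predictor is combinatorially infeasible; this package instead learns a
direct inverse map.

## The two-module model

Two graph neural networks share one node-feature encoding scheme:

* **Response module** `f_r` (`responseModel()`, `responseForward()`): maps
  an initial expression state plus per-node perturbation flags to the
  predicted post-perturbation state in `[0,1]^n`, message-passing on the
  graph mutilated by the intervention (flagged nodes lose their incoming
  arcs). This is the learned analogue of evaluating the SCM's structural
  equations in topological order.
* **Discovery module** `f_p` (`perturbagenModel()`,
  `perturbagenForward()`): given the diseased and treated states, scores
  every node for membership in the intervention set that explains the
  transition, and returns a tie-broken ranking. The top-N prefix
  (N = true target-set size, when known) is the predicted perturbagen.
  `f_p` runs on the unmutilated graph: the intervention set is exactly
  what is unknown at inference time.

**Node features.** Each node contributes three learnable `d`-dimensional
embeddings, concatenated to a `3d` feature (per-node tables, shared across
samples): a perturbation-flag embedding (two rows per node; soft flags
`f ∈ [0,1]` interpolate `(1-f)·E0 + f·E1`), a bin embedding of the
expression value (per-gene thresholds at `B-1` equally spaced quantiles of
the training expression, `fitBins()`; a value falls in bin
`1 + #{thresholds < value}`, so constant genes collapse to the first bin),
and a positional embedding. `f_p` replaces the flag embedding with a second
expression-bin embedding, since its two scalar inputs per node are the
diseased and treated values. Per-gene thresholds are the default; pooled
global thresholds are available (`fitBins(global = TRUE)`).

**Message passing.** `K` layers of
`h_i' = ReLU(W_self h_i + W_nei ⊕_{j∈Pa(i)} h_j + b)` with mean
aggregation over in-neighbors by default (sum available). This is the
simplest instantiation of the general message/aggregate/update layer; a
two-layer feedforward head maps the final embedding to a logistic output
(`f_r`) or an unbounded score (`f_p`). With `K = 0` the head alone is used
and the graph is ignored — a useful ablation.

## Objectives and training

`f_r` minimizes a continuous-target cross-entropy
`-(t log p + (1-t) log(1-p))`, averaged over nodes and samples, over
treatment triplets (diseased → treated under the known perturbagen) and
optionally disease triplets (healthy → diseased under the disease genes;
`useDiseaseData`). Predictions are clipped to `(1e-12, 1-1e-12)` before the
logs.

`f_p` minimizes, per `lossMode`:

* **super** — weighted binary cross-entropy of `sigmoid(scores)` against
  the true intervention indicator, positives up-weighted by `n/|U'|`
  (without this, the ~n-to-few class imbalance lets the all-negative
  solution dominate);
* **cycle** — the response loss between the true treated state and the
  *frozen* `f_r`'s prediction under the discovered soft flags
  `sigmoid(scores)`. The discrete "mutilate by the predicted set" step is
  relaxed: the soft pass keeps the intact graph and interpolates the flag
  embedding, which is the minimal differentiable path from `f_p`'s scores
  into `f_r`'s input. No gradient ever reaches `f_r`'s parameters;
* **supercycle** (default) — their unweighted sum.

The two modules train "in parallel" as interleaved per-epoch Adam updates
(`f_r` step, then `f_p` step with `f_r` frozen) — the contract is ordering
and freezing, not concurrency. Each module early-stops independently: its
validation loss must improve by at least `minDelta = 1e-5` within
`patience = 15` consecutive epochs, and the reported module is its
best-validation snapshot. A non-finite training loss aborts with the epoch
number.

Splits follow the standard protocol: 5-fold cross-validation with a seeded
8:2 train/validation subdivision inside each training portion
(`makeRandomSplits()`), and leave-cell-out splits that train within one
context and test on every sample of all others (`makeLeaveCellOut()`).
`gridSearchK()` selects the GNN depth from `KGrid` by validation nDCG
(ties to the smaller depth, per fold).

**Optimizer defaults.** The model constructors default to `d = 16`,
`B = 5`, head width `2d`, two prediction layers. The pipeline
(`defaultRunConfig()`) trains with `d = 8`, Adam at `lr = 0.01`, minibatches
of 128 and `maxEpochs = 25`: on the reference simulation below, full-batch
small-learning-rate training needs several hundred epochs to reach the same
held-out accuracy that minibatched Adam reaches within ~20, with no
measurable quality difference (held-out percent-accurately-predicted ~88 in
both regimes). These were fixed by watching training/validation loss
curves. All of it is configurable through `trainConfig()`.

## The simulator: what it emulates, and what it does not

`sampleSCM()` draws a random DAG (random node order, forward arcs kept with
probability `arcDensity`) with arc weights uniform on `±[0.5, 2]` and
biases uniform on `[-1, 1]`. States follow logistic-linear structural
equations with additive Gaussian exogenous noise,
`x_i = logistic(Σ_j w_ij x_j + b_i + ε_i)`, evaluated in topological order
on the mutilated graph (`simulateState()`); the logistic keeps states in
`[0, 1]`, matching normalized expression, and admits closed-form checks.

Disease triplets pair an unperturbed draw with the same draw under the
disease-gene intervention (`generateDiseaseDataset()`); treatment triplets
pair a diseased draw with the same exogenous draw under the perturbagen
intervention alone (`generateTreatmentDataset()`). Sharing the exogenous
draw within a pair (`sharedNoise = TRUE`, default) makes pairs differ only
through the intervention; the alternative interpretation (independent
draws) is one flag away, since real paired profiles do not reveal how much
exogenous variation they share. Intervention clamp values default to strong
per-gene up- or down-shifts — `Beta(5, 0.5)` or `Beta(0.5, 5)` draws with a
fixed per-gene direction — emulating activation/knockout without hard
0/1-only states; explicit clamps are supported (that is how the
exact-reversal identity, treating the disease genes at their healthy
values, restores the healthy state to machine precision at zero noise).

Corruptions mirror three robustness settings: progressive removal of bridge
edges (`removeBridgeEdges()`; bridges disconnect parts of the network),
removal of random edges (`removeRandomEdges()`), and latent-confounder
noise (`injectConfounders()`): genes partitioned into 50 contiguous
near-equal index blocks, each block given its own Gaussian with mean from
`[-0.5, 0.5]` and sd from `[0.1, 0.5]`, a seeded fraction of blocks
selected, every expression value of their genes incremented by a fresh draw
and clamped to `[0, 1]`. The mean range is read as `[-0.5, 0.5]`: a
degenerate single-point range would contradict the premise of *distinct*
group means. Contiguous index blocks stand in for "predefined" gene groups
for reproducibility.

The simulator is i.i.d. by design: no assay artifacts, dose or time
covariates, replicate structure, or cell-type heterogeneity. Passing tests
on it demonstrates that the implementation is faithful and that the method
identifies interventions when the generative assumptions hold — not that it
will match real-data performance, which requires real perturbational
compendia and networks.

## Evaluation and statistics

* `ndcg()`: gain `1 - rank/n` per true target, discount `1/log2(rank+1)`
  (the standard information-retrieval discount; the discount changes
  absolute values, so it is fixed and documented), normalized by the ideal
  ranking.
* `recallAtK()` at 1/10/100; `accuratelyPredicted()` — top-N (N = per-sample
  true set size) intersects the truth; reported as a percentage over
  samples.
* `samplewiseR2()` / `perturbagenwiseR2()` — squared Pearson correlation of
  a predicted state, and of per-gene means over a perturbagen's sample set;
  `evaluateModels()` also reports the closed-loop `reconstructionR2`:
  `f_r`'s prediction under the *predicted* top-N set against the observed
  treated state.
* `networkProximity()` — mean shortest-path distance over all
  predicted×true pairs on the undirected view. Disconnected pairs are
  excluded and counted (attribute `"excluded"`); a closest-node variant
  sits behind `closest = TRUE` and is off by default.
* `proximityTest()` — one-sided Mann–Whitney U (alternative: the method's
  distances are smaller than random). `U` counts pairs where the method
  value is smaller (ties half), so the rank-biserial
  `r = 2U/(n1 n2) - 1` is positive when predictions are closer to the true
  targets than chance. The p-value is an exact permutation enumeration
  whenever `choose(n1+n2, n1) ≤ 20000`, otherwise a tie-corrected normal
  approximation with continuity correction. The 95% CI of `r` is a
  percentile bootstrap over 1,000 resamples.
* `aggregateAndTest()` — mean over all metric values per method (metrics on
  the percent scale are divided by 100 first so no single metric dominates
  the average), with paired fold-wise t-tests: one-tailed for benchmarking
  the focal method, two-tailed for ablation comparisons, α = 0.05. A single
  fold yields `NA` (no test possible); a constant non-zero fold difference
  is reported at the smallest positive double, the zero-variance limit of
  the paired t.
* Baselines: `baselineRank()` (seeded random permutation, or a prior gene
  list at the top with a shuffled remainder) and `indirectRank()` (drugs
  sorted by R², ties broken lexicographically; targets expanded in seeded
  random order, first occurrence kept; genes missing from every drug
  appended shuffled).

## Numerical choices and degenerate inputs

Confidence filtering uses the linear-interpolation (type 7) quantile with a
strict `<` cut: at quantile 0.5 over confidences `0.1..1.0` the cut is
0.55 and five of ten arcs survive. Edge-removal counts use
`floor(fraction × #edges)` on the undirected edge set, deleting both arcs
of a doubled edge. Ranking ties default to ascending node index (a seeded
shuffle is available) so reruns are identical. Constant genes bin to a
single value; constant vectors make Pearson R² undefined and are reported
as `NA` rather than silently dropped. All randomness flows through explicit
seeds, with named child seeds derived from one root so that independent
procedures never share a stream.

## Problem sizes used by the test suite and acceptance script

The reference conditions are a 60-gene SCM at arc density 0.08, noise sd
0.05, 3 disease genes, a 20-perturbagen library of 1–3-gene target sets, 40
treatment samples per perturbagen (800 total) and 100 disease samples;
training uses 5-fold cross-validation with the depth grid `{1, 2}` and the
pipeline defaults above. The acceptance suite repeats this over three
seeds, runs single-fold ablations (super / cycle / supercycle at the
selected depth) and a single-fold confounder sweep at fractions
`{0.2, 0.6, 1.0}`; metric and statistics oracles run at up to 50 nodes and
1,000 random instances. These sizes are the package's reference scale for a
single workstation CPU; everything scales up through the configuration.

## Known limitations

* The GNN engine is purpose-built (dense BLAS + sparse block-diagonal
  aggregation with an RcppArmadillo hot path), not a general autodiff
  framework: layer shapes are fixed to the architecture described here, and
  aggregation supports mean and sum (not max).
* Desk-scale only: no GPU, no distributed training, constant learning rate.
* The simulator's acyclic SCM cannot represent feedback loops; real
  regulatory networks have them. Message passing on doubled undirected
  edges partially compensates but is not a model of dynamics.
* Real-data preprocessing (expression normalization pipelines, network
  assembly from interaction databases, drug–target curation) is out of
  scope; inputs are assumed already normalized to `[0, 1]` with a ready
  edge list.
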