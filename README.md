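# perturbDiscover

Combinatorial perturbagen discovery on proxy causal gene networks: given
paired diseased/treated expression states, predict the **set of genes**
whose perturbation shifts cells from the diseased toward the treated state.

The package is aimed at computational biologists studying cellular response
to perturbations who want a causally-grounded, trainable inverse model —
plus a fully self-contained simulator so every component can be exercised
and tested without external downloads.

## The method

Cells are modeled as a structural causal model over genes; a perturbagen is
a do-intervention on its target set *U′*, implemented as **edge
mutilation**: arcs into intervened nodes are deleted (their values are set
exogenously) while outgoing arcs keep propagating effects. On a proxy
causal graph *G* (PPI- or GRN-like), two graph neural networks are trained
jointly:

- a **response module** *f_r*(x, U) → x′ predicting the post-perturbation
  state on the mutilated graph *G_U*, trained with continuous-target
  cross-entropy on disease triplets ⟨x_h, U, x_d⟩ and treatment triplets
  ⟨x_d, U′, x_t⟩;
- a **discovery module** *f_p*(x_d, x_t) → per-gene scores, whose top-N
  prefix is the predicted perturbagen, trained with

  L(f_p) = CE(x_t, f_r(x_d, f_p(x_d, x_t))) + CE(1_{U′}, f_p(x_d, x_t)),

  a **cycle-consistency** term through the frozen response module plus a
  class-weighted **supervision** term (modes: `super`, `cycle`,
  `supercycle`).

Node features concatenate three learnable per-node embeddings
(perturbation flag, quantile-binned expression, positional); evaluation
uses nDCG with gain 1 − rank/n, recall@{1,10,100}, percent accurately
predicted samples, sample-/perturbagen-wise R², and network proximity
d(P,R) = mean pairwise shortest-path distance with a one-sided
Mann–Whitney U test and rank-biserial effect size. See the methods
vignette (`vignettes/perturbDiscover-methods.Rmd`) for the full account.

## Worked example

Simulate the reference study (60-gene SCM, 3 disease genes, 20 perturbagens
of 1–3 genes, 40 treatment samples each), train with 5-fold
cross-validation and a GNN-depth grid of {1, 2}, and evaluate held-out
folds against the random baseline:

```r
library(perturbDiscover)
cfg <- defaultRunConfig(outDir = NULL, seed = 11)
trained <- runTrain(cfg, write = FALSE)          # ~2 min on one CPU
sapply(trained$fits, `[[`, "K")                  # depth selected per fold
#> fold1 fold2 fold3 fold4 fold5
#>     2     1     2     1     2
ev <- runEvaluate(cfg, trained, write = FALSE)
aggregate(cbind(ndcg, pctAccuratelyPredicted) ~ method,
          data = ev$summary, FUN = mean)
#>   method      ndcg pctAccuratelyPredicted
#> 1  model 0.7773991                 72.500
#> 2 random 0.1775673                  7.125
ev$proximity[c("p", "rankBiserial")]
#> $p
#> [1] 5.622211e-81
#> $rankBiserial
#> [1] 0.5463078
```

Reading: on held-out samples the trained discovery module's top-N predicted
targets hit the true target set for 72.5% of samples versus 7.1% for a
random ranking, its mean nDCG is 0.78 versus 0.18, and its predicted
targets sit significantly closer to the true targets in the network than
random predictions (rank-biserial +0.55, one-sided Mann–Whitney
p ≈ 6e-81). Exact numbers vary with the seed.

Lower-level surfaces: `loadEdgeList()` / `mutilate()` / `findBridges()` /
`removeBridgeEdges()` (graphs), `sampleSCM()` / `simulateState()` /
`generateTreatmentDataset()` / `injectConfounders()` (simulator),
`responseForward()` / `perturbagenForward()` (models), `trainModel()` /
`gridSearchK()` (training), `ndcg()` / `networkProximity()` /
`proximityTest()` / `baselineRank()` (evaluation), and `runBenchmark()` for
robustness sweeps over edge-removal, confidence-filter and confounder
schedules. A thin CLI lives at `inst/scripts/pdisco.R`
(`Rscript pdisco.R simulate|train|evaluate|benchmark --config run.yaml`).

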