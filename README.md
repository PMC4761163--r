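# phyloniche

Phyloclimatic modeling of ecological niche evolution: does speciation in a
clade go hand in hand with **niche conservatism** (close relatives keep
more similar climatic niches than their available environments would
predict) or with **niche divergence**?  `phyloniche` is aimed at
evolutionary ecologists who have presence-only occurrence records, gridded
environmental layers, and a time-calibrated phylogeny, and want to run the
full battery of phyloclimatic analyses — from niche models to
disparity-through-time — in one reproducible R workflow.  A built-in
synthetic-data generator produces complete studies with known truth, so
every stage can be validated without downloading real climate layers.

## The methods in brief

- **Maximum-entropy niche models.**  For each species the fitted suitability
  surface is the Gibbs distribution `p(i) ∝ exp(λ·f(i))` over grid cells
  that minimizes the L1-penalized negative log-likelihood of the presences,
  `log Z(λ) − λ·f̄ + Σⱼ βⱼ|λⱼ|`, with standardized linear and quadratic
  features, `βⱼ = β·sd(fⱼ)/√m`.  At the optimum
  `|E_p[fⱼ] − f̄ⱼ| ≤ βⱼ` (KKT).  Logistic output
  `τ·e^H·pᵢ / (1 − τ + τ·e^H·pᵢ)` with entropy `H` and prevalence
  `τ = 0.5`; models are screened by replicate train/test AUC and
  thresholded at the minimum training presence.
- **Niche overlap and hypothesis tests.**  Schoener's
  `D = 1 − ½Σ|pX − pY|` and Warren's `I = 1 − ½Σ(√pX − √pY)²` on
  normalized surfaces; a niche **identity test** (pooled occurrences,
  random repartition, refit) and a **background-similarity test**
  (pseudolocalities drawn from a species' available environment), each
  with empirical percentile bounds from 100 replicates at 95 % confidence.
- **Niche evolution through time.**  Predicted niche occupancy (PNO)
  profiles binned along each environmental axis (mass sums to 1);
  ancestral tolerances via maximum-likelihood Brownian-motion
  reconstruction over repeated draws from the PNOs; age-range correlation
  (OLS of per-node cross-clade overlap on node age, permutation-tested);
  disparity-through-time curves with the MDI statistic against a
  Brownian simulation envelope; phylogenetic PCA on the evolutionary
  covariance matrix and phylogenetic MANOVA with a Brownian null for the
  Wilks/F statistic.

## Worked example

Simulate a study with two major clades — one evolving under
Ornstein–Uhlenbeck attraction to the ancestral optimum (conservatism), one
under Brownian motion (divergence) — then fit models and test:

```r
library(phyloniche)

ds <- simulateDataset(nSpecies = 8, nClades = 2, regimes = c("OU", "BM"),
                      nRows = 20, nOcc = 25, seed = 42)

models <- lapply(ds$occurrences, fitMaxent, stack = ds$stack)
models[["t1"]]
#> NicheModel: 't1' (6 features over env1, env2, env3)
#>   entropy 4.5293 | MTP 0.0756 | converged after 18 sweep(s)

evaluateAUC(ds$stack, ds$occurrences[["t1"]], seed = 1)$meanAUC
#> [1] 0.936875

ov <- nicheOverlap(models)
ov
#> OverlapMatrix: 8 species (logistic surfaces)
#>   mean D 0.514 | mean I 0.755

sisters <- names(ds$clades)[ds$clades == "clade1"][1:2]
backgroundTest(ds$stack, ds$occurrences[[sisters[1]]],
               ds$occurrences[[sisters[2]]], seed = 1)
#> background test: t1 vs t5 (A->B), metric D
#>   observed D = 0.7719 | null bounds [0.4102, 0.5105] (100 reps, conf 0.95)
#>   verdict: conservatism (p = 0.010)

ageRangeCorrelation(ds$tree, ov, seed = 1)
#> Age-range correlation (ft weighting, D metric): slope -0.292, intercept 0.7637
#>   permutation p = 0.027 | 7 node(s), 0 outlier(s)
```

Reading the output: the two OU sisters overlap far more (`D = 0.77`) than
models fitted to random draws from their shared background (null upper
bound `0.51`), the signature of niche conservatism; and overlap declines
with node age (negative ARC slope, permutation `p = 0.027`), i.e. niche
differences accumulate with divergence time.  `runPipeline()` chains all
stages (thinning, variable decorrelation, models, tests, PNO, ancestral
tolerances, ARC, DTT/MDI, pPCA/MANOVA) from one configuration with fully
derived seeds, and writes TSV/JSON artifacts plus a manifest.

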