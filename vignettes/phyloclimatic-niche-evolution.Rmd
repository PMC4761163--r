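---
title: "Phyloclimatic analysis of niche conservatism and divergence"
author: "phyloniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phyloclimatic analysis of niche conservatism and divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloniche)
```

`phyloniche` asks a comparative question of distribution data: as a clade
diversified, did related species retain similar environmental niches
(conservatism) or move apart in niche space (divergence)?  This vignette
is the package's own account of the models it fits, the conventions it
adopts where the methodology is genuinely open, and what its synthetic
tests do and do not establish about real data.

## Data model

Environmental layers live on one co-registered grid (ESRI ASCII
convention: row 1 is the northernmost row; cells are half-open in x,
top-inclusive in y).  The validity mask is the *union* of the per-layer
nodata cells, so every analysis — model fitting, overlap, PNO — sees a
single common support; this keeps all per-cell distributions comparable.
Occurrences are per-species point sets in map units; phylogenies are
ultrametric, binary `ape::phylo` objects whose tip labels match the
species names.  Ultrametricity is verified to a relative tolerance of
`1e-6` of the tree depth and trees are otherwise used as given.

Before modeling, occurrences can be thinned to a minimum separation
(greedy, first-record-wins, Euclidean distance in map units — the
threshold is configuration, typically the grid resolution), and variables
are decorrelated: visiting variables in a caller-supplied priority order
(encode "extremes before averages" there), a variable is kept only if its
absolute Pearson correlation with every already-kept variable stays at or
below the threshold (default `r = 0.9`, computed over the common
support).  Greedy filtering by an explicit priority makes the retained
set independent of the order the files were read in.

## The niche model

The ecological niche model is a presence-only maximum-entropy (Gibbs)
model over the non-masked cells,

$$p_\lambda(i) = \frac{\exp(\lambda \cdot f(i))}{Z(\lambda)},$$

with features `f` the standardized linear and quadratic terms of each
retained variable.  Restricting the feature set to linear + quadratic is a
deliberate simplification of the historical maximum-entropy SDM tooling
("auto features" with hinge/threshold/product classes): it keeps the
program a small, fully specified convex optimization while still
expressing unimodal (optimum + breadth) responses, which is exactly the
niche geometry the downstream tolerance reconstructions assume.  Feature
standardization uses the *background* mean and SD, so models fitted to
different occurrence sets share one feature space — a prerequisite for the
pooled refits of the identity test.

The weights minimize the penalized negative log-likelihood
$\log Z(\lambda) - \lambda \cdot \bar f + \sum_j \beta_j |\lambda_j|$ with
$\beta_j = \beta\, s_j / \sqrt{m}$ ($s_j$ = feature SD over the $m$
presences; multiplier $\beta$ defaults to 1 and is configurable).  The
optimizer is cyclic coordinate descent with a soft-threshold Newton step
and per-update backtracking on the true objective, so the objective trace
is non-increasing by construction; convergence is declared when a full
sweep changes the objective by less than `1e-6` (default cap 1000
sweeps).  The contract is the solution, not the algorithm: at the optimum
the KKT conditions bound each feature discrepancy,
$|E_p[f_j] - \bar f_j| \le \beta_j$, and the test suite checks the fitted
model against a direct constrained-entropy optimization on small grids.

Outputs: the raw distribution (sums to 1 over the support), and the
logistic transform $\tau e^H p_i / (1 - \tau + \tau e^H p_i)$ with $H$
the entropy of `p` and prevalence $\tau = 0.5$ (the conventional default),
written so that a featureless model scores $\tau$ everywhere.  Model
adequacy uses replicate subsampling (default 10 replicates, 59 % train /
41 % test) with a rank-based AUC of test presences against all background
cells and a mean-AUC gate of 0.7; suitability maps are thresholded at the
minimum training presence.  Species with fewer than 5 occurrences are
excluded from all niche analyses — the conventional floor below which
presence-only models are not trusted — and the exclusion is surfaced as a
typed condition so pipelines can log it.

## Overlap and the randomization tests

Overlap uses Schoener's *D* and Warren's *I* on suitability surfaces
renormalized to sum 1.  The package standardizes the *logistic* surface by
default (the common convention; the raw surface is available via
`surface = "raw"`).  *I* provably dominates *D*, so both are reported.

The **identity test** pools the two occurrence sets, repartitions at
random into pseudo-samples of the original sizes, and refits both models;
identity is rejected when the observed overlap falls below the one-sided
lower bound.  The **background test** holds species A's model fixed and
refits against pseudolocality cells drawn (without replacement) from B's
background; observed overlap above the upper bound is conservatism, below
the lower bound divergence.  Both one-sided directions reflect the
directional hypotheses being asked (more, or less, overlap than the
environment predicts); each ordered direction of a pair is run
separately.  Defaults are 100 replicates at 95 % confidence.  Percentile
bounds are empirical order statistics without interpolation (rank
$\lceil q(n+1) \rceil$), so 100 replicates give exact attained levels; a
failed replicate fit is redrawn, capped at three times the budget.

A species' "background" is not uniquely defined by the method's
literature.  The default here is the convex hull of its occurrences
buffered by 5 cells, intersected with the common support; any mask
(including the full study extent) can be supplied instead, and the
package's own calibration suites exercise both choices.

## Niche evolution through time

**PNO profiles** rebin a model's suitability mass along one variable into
50 equal-width bins spanning the variable's range over the support —
edges are global per variable, so profiles are comparable across species —
and therefore sum to 1.  **Ancestral tolerances** draw, per Monte-Carlo
sample (default 100), one value per tip from its PNO (bin midpoints with
bin-mass probabilities) and compute maximum-likelihood Brownian-motion
ancestral states — the GLS solution minimizing
$\sum_{edges} (\Delta x)^2 / \ell$, solved by one dense weighted-Laplacian
solve and applied to all samples as a single linear operator.  Sampling
midpoints rather than uniform-within-bin values keeps the sample space
finite and exactly reproducible; with 50 bins the discretization is well
below the reconstruction uncertainty.

**Age-range correlation** summarizes each internal node by the weighted
mean overlap of the tip pairs whose MRCA it is — default weighting halves
a pair's contribution per intervening internal node ("ft"), with the
unweighted mean as an option — and regresses node overlap on node age.
Nodes are flagged against a per-node 95 % *prediction* interval (the
choice that makes individual-node outlier calls meaningful; a
mean-response confidence band is available via `interval =
"confidence"` and flags fewer nodes).  Slope significance comes from
permuting tip identities of the overlap matrix (default 1000
permutations, two-sided).

**Disparity through time** standardizes each lineage's subclade disparity
(mean squared pairwise distance, `2·var`) by the whole-clade disparity
and averages over the lineages crossing just *before* each node's split,
from the root (value exactly 1) to the present (value 0, appended at
relative time 1); the curve is evaluated per environmental variable on
the PNO weighted means and is invariant to affine transformation of the
trait.  **MDI** is the trapezoid area between the observed curve and the
pointwise mean of Brownian simulations (default 1000; median optional)
whose rate is the GLS phylogenetic variance of the observed tips —
negative MDI means disparity sits among subclades (conservatism within
them).  Per-node significance uses the rank of the observed node
disparity among the simulated values; because whether such node calls
should be one- or two-tailed is itself a modeling choice, both the
two-tailed and the high-disparity one-tailed p-value are reported.  Ranks
are midranks under ties so the root (always exactly 1) can never appear
significant.

**Multivariate structure** of the PNO weighted means uses phylogenetic
PCA: GLS phylogenetic mean, evolutionary covariance
$R = (X-1a')'C^{-1}(X-1a')/(N-1)$, eigendecomposition, scores on the
centered data.  Because the variables carry heterogeneous units (degrees,
centimeters, unitless indices), the default scales each variable by its
evolutionary SD (`mode = "corr"`); covariance mode is available and, on a
star phylogeny, reduces exactly to ordinary PCA.  The phylogenetic MANOVA
takes the leading components (default 4, configurable), computes the
ordinary Wilks/exact-F statistic for the grouping factor, and builds the
null by simulating multivariate Brownian traits on the tree (rate matrix
= the GLS estimate) with labels held fixed — the simulation happens
directly on the analyzed scores; simulating raw variables and
re-projecting would be the alternative, but the scores are the quantities
the test is defined on.

## The synthetic generator

The generator is first-class, tested code that defines the package's
study conditions.  Environmental layers are Gaussian-smoothed white noise
(kernel SD = the autocorrelation length, default 3 cells), standardized,
mixed by the Cholesky factor of a target correlation matrix (default
exchangeable 0.4 — climate layers are never independent), and rescaled to
0–100.  Trees are forward-simulated pure-birth (Yule) processes rescaled
to depth 1, since the temporal analyses operate on relative time.  Niche
optima evolve from mid-range root values along the tree: Brownian motion
with rate 900 (units² per unit depth, i.e. tip SD 30 on a 0–100 scale —
strong divergence), or Ornstein–Uhlenbeck with the same rate and
`alpha = 10` toward the clade-MRCA optimum (stationary SD ≈ 6.7 —
conservatism); breadths stay fixed at 12.  Suitability is the product of
per-variable Gaussian responses — the simplest unimodal niche consistent
with reconstructing tolerances, and analytically available to tests —
and occurrences (default 30 per species) sample cells proportional to it,
uniformly within the cell.  One master seed drives every stage through
name-hashed substreams, so stages re-run independently yet reproducibly.

What the generator does *not* emulate: real topography or drainage
structure, sampling bias and spatial clustering of collection effort,
niche breadth evolution, interactions between variables beyond linear
correlation, or detection error.  Passing calibration on these surfaces
therefore shows the machinery is statistically sound under its own
assumptions — not that any particular empirical dataset meets them.

## Calibration and problem sizes

The acceptance suite validates the statistical behavior on generator
truth at sizes chosen to keep a full run in a few minutes on one core:
identity-test level and p-value uniformity over 200 simulated null
datasets (15 × 15 grid, two layers, 25 + 25 occurrences, 100 replicates
each); MDI centering and node-p uniformity over 200 Brownian datasets on
a 12-tip tree (200 simulations per dataset); MANOVA type-I over 200
datasets on a 21-tip tree; ARC sign recovery over 50 Brownian-divergence
studies (8 species each); and background-test power over 50 replicates
per scenario (strong OU toward a shared optimum vs optima at opposite
extremes, full-landscape backgrounds).  The reference study recomputed by
`scripts/acceptance.R` uses 12 species in three clades (OU, OU, BM) on a
30 × 30 grid with the full default settings (100 test replicates, 1000
DTT and MANOVA simulations).

## Limitations

- Only linear + quadratic features: strongly skewed or bimodal responses
  are approximated by their best unimodal fit.
- Backgrounds are a convention (buffered hull by default); conclusions of
  the background test can shift with the extent, which is why it is
  exposed as an argument rather than fixed.
- The BM machinery (ancestral states, DTT null, MANOVA null) assumes
  homogeneous-rate Brownian evolution; OU exists only in the generator,
  deliberately, as the conservatism scenario to detect — not as a fitted
  model.
- No CRS handling: all inputs must be co-registered on one projected
  grid.
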