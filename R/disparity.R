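# Relative disparity-through-time curves and the MDI statistic against a
# Brownian-motion simulation envelope.

# Curve evaluation shared by observed and simulated traits.  For each
# internal node, taken in order of increasing height, the curve value is
# the mean over the lineages crossing just BEFORE that node's split of
# (subclade disparity / whole-clade disparity); the final point, at the
# present, is 0 (every lineage is then a single tip).  Works column-wise on
# a tips x nSims matrix of trait values.
.dttSetup <- function(tree) {
  n <- ape::Ntip(tree)
  depth <- checkUltrametric(tree)
  bt <- ape::branching.times(tree)
  nodeTime <- depth - bt               # split times measured from the root
  ord <- order(nodeTime, as.integer(names(nodeTime)))
  tipSets <- .descendantTipSets(tree)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  list(n = n, depth = depth,
       nodeIds = as.integer(names(nodeTime))[ord],
       nodeTime = unname(nodeTime)[ord],
       tipSets = tipSets, children = children)
}

.dttCurves <- function(setup, X) {
  X <- rbind(X)                         # tips x nSims, rows in tip-id order
  nSims <- ncol(X)
  nNodes <- length(setup$nodeIds)
  # subclade disparity per node, per simulation
  disp <- matrix(0, setup$n + length(setup$nodeIds), nSims)
  for (v in c(setup$nodeIds)) {
    tips <- setup$tipSets[[v]]
    if (length(tips) > 1L)
      disp[v, ] <- 2 * apply(X[tips, , drop = FALSE], 2L, stats::var)
  }
  whole <- disp[setup$nodeIds[1], ]     # root subclade = whole clade
  if (any(whole == 0))
    stop("whole-clade disparity is zero: degenerate trait values")
  out <- matrix(NA_real_, nNodes + 1L, nSims)
  lineages <- setup$nodeIds[1]          # the root lineage
  for (k in seq_len(nNodes)) {
    v <- setup$nodeIds[k]
    rel <- disp[lineages, , drop = FALSE] / rep(whole, each = length(lineages))
    out[k, ] <- colMeans(rel)
    lineages <- c(lineages[lineages != v], setup$children[[as.character(v)]])
  }
  out[nNodes + 1L, ] <- 0               # at the present all lineages are tips
  out
}

#' Disparity-through-time curve
#'
#' At each internal-node height (root first) the mean, over all lineages
#' crossing that time, of the lineage's subclade disparity standardized by
#' the whole-clade disparity; see [disparityOf()].  The curve equals 1 at
#' the root and is reported on relative time (0 = root, 1 = present, with
#' a terminal point of 0 at the present).  The curve is invariant to affine
#' transformation of the trait values.
#'
#' @param tree an ultrametric \code{phylo}
#' @param tipValues numeric vector named by tip label (or in tip order)
#' @return data frame with columns \code{time} (relative) and
#'   \code{disparity}
#' @export
dttCurve <- function(tree, tipValues) {
  if (!is.null(names(tipValues))) tipValues <- tipValues[tree$tip.label]
  setup <- .dttSetup(tree)
  obs <- .dttCurves(setup, matrix(tipValues, ncol = 1))
  data.frame(time = c(setup$nodeTime, setup$depth) / setup$depth,
             disparity = obs[, 1])
}

#' MDI: disparity-through-time against a Brownian-motion null
#'
#' Simulates \code{nSims} Brownian-motion trait sets on the tree (rate =
#' GLS estimate from the observed tips, see [bmRate()], unless given),
#' computes their disparity curves, and summarizes: MDI is the trapezoid
#' area between the observed curve and the pointwise mean simulated curve
#' over relative time -- negative when observed disparity lies below the
#' Brownian expectation (disparity partitioned among subclades, i.e.
#' conservatism within them), positive when above (disparity within
#' subclades).  The envelope is the pointwise
#' \code{(1-conf)/2, (1+conf)/2} band.  Each internal node also receives
#' the rank r of its observed disparity among the S simulated values
#' (midrank under ties, so the degenerate root never looks significant), a
#' two-tailed p-value \code{2 min(r, S+1-r) / (S+1)} and the one-tailed
#' (high-disparity, i.e. divergence) p-value.
#'
#' @param tree an ultrametric \code{phylo}
#' @param tipValues numeric vector named by tip label (or in tip order)
#' @param nSims number of BM simulations (>= 100; default 1000)
#' @param conf envelope confidence (default 0.95)
#' @param rate optional BM rate for the null (default: estimated)
#' @param center "mean" (default) or "median" simulated expectation
#' @param seed integer seed
#' @return a [DTTCurve-class]
#' @export
mdi <- function(tree, tipValues, nSims = 1000, conf = 0.95, rate = NULL,
                center = c("mean", "median"), seed = NULL) {
  stopifnot(nSims >= 100)
  center <- match.arg(center)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(names(tipValues))) tipValues <- tipValues[tree$tip.label]
  setup <- .dttSetup(tree)
  obs <- .dttCurves(setup, matrix(tipValues, ncol = 1))[, 1]
  if (is.null(rate)) rate <- bmRate(tree, tipValues)$rate
  sims <- bmSimulate(tree, rootValue = 0, rate = rate, nSims = nSims)
  simCurves <- .dttCurves(setup, sims[tree$tip.label, , drop = FALSE])
  simMean <- if (center == "mean") rowMeans(simCurves)
             else apply(simCurves, 1L, stats::median)
  qs <- t(apply(simCurves, 1L, stats::quantile,
                probs = c((1 - conf) / 2, (1 + conf) / 2)))
  times <- c(setup$nodeTime, setup$depth) / setup$depth
  mdiVal <- trapezoid(times, obs - simMean)
  S <- nSims
  nodeRows <- seq_along(setup$nodeIds)
  # midrank of the observed value among the simulations: ties (e.g. the
  # root, where every curve equals 1) share rank, and the two-tailed
  # p-value stays within (0, 1]
  r <- vapply(nodeRows, function(k)
    sum(simCurves[k, ] < obs[k]) + (sum(simCurves[k, ] == obs[k]) + 1) / 2,
    numeric(1))
  nodes <- data.frame(node = setup$nodeIds, time = times[nodeRows],
                      observed = obs[nodeRows], rank = r,
                      pTwoTailed = pmin(1, 2 * pmin(r, S + 1 - r) / (S + 1)),
                      pHigh = vapply(nodeRows, function(k)
                        (1 + sum(simCurves[k, ] >= obs[k])) / (S + 1), numeric(1)))
  new("DTTCurve", times = times, observed = obs, simMean = simMean,
      lower = qs[, 1], upper = qs[, 2], mdi = mdiVal, nodes = nodes,
      nSims = nSims, conf = conf)
}
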