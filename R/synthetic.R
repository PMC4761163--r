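# Synthetic-data generators: spatially autocorrelated, inter-correlated
# environmental surfaces; pure-birth ultrametric trees; species niche optima
# evolving along the tree under Brownian motion (divergence) or
# Ornstein-Uhlenbeck (conservatism); occurrence points sampled proportional
# to true suitability.  Everything is deterministic given a seed.

# Truncated-Gaussian smoothing along one dimension with edge
# renormalization; `len` is the kernel SD in cells.
.smoothDim <- function(M, len, byRow) {
  if (len <= 0) return(M)
  h <- max(1L, ceiling(3 * len))
  k <- stats::dnorm(-h:h, sd = len)
  if (byRow) M <- t(M)
  nr <- nrow(M)
  acc <- matrix(0, nr, ncol(M)); wt <- numeric(nr)
  for (o in -h:h) {
    w <- k[o + h + 1L]
    src <- seq_len(nr) + o
    ok <- src >= 1L & src <= nr
    acc[ok, ] <- acc[ok, ] + w * M[src[ok], , drop = FALSE]
    wt[ok] <- wt[ok] + w
  }
  out <- acc / wt
  if (byRow) t(out) else out
}

#' Simulate correlated environmental grids
#'
#' Each variable starts as white noise, is smoothed with a Gaussian kernel
#' of SD \code{autocorrLength} cells (0 = i.i.d. cells), standardized, then
#' the variables are linearly mixed by the Cholesky factor of the target
#' correlation matrix and affinely rescaled to \code{varRanges}.  The
#' sample inter-variable correlation therefore matches the target up to
#' Monte-Carlo error.
#'
#' @param variables variable names
#' @param nRows,nCols grid dimensions
#' @param autocorrLength spatial autocorrelation length in cells (>= 0)
#' @param targetCorr target correlation matrix (symmetric PSD, unit
#'   diagonal), or a single off-diagonal value for an exchangeable matrix
#' @param varRanges 2-column matrix (or length-2 vector recycled) of target
#'   min/max per variable
#' @param xll,yll,cellsize geotransform of the output grid
#' @param maskFraction fraction of cells randomly flagged nodata
#' @param seed integer seed
#' @return an [EnvStack-class]
#' @export
simulateEnvStack <- function(variables = c("env1", "env2", "env3"),
                             nRows = 30, nCols = nRows,
                             autocorrLength = 3, targetCorr = 0.4,
                             varRanges = c(0, 100),
                             xll = 0, yll = 0, cellsize = 1,
                             maskFraction = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(variables)
  if (length(targetCorr) == 1L) {
    targetCorr <- matrix(targetCorr, p, p)
    diag(targetCorr) <- 1
  }
  if (!isSymmetric(unname(targetCorr)) || any(diag(targetCorr) != 1))
    stop("targetCorr must be symmetric with unit diagonal")
  ev <- eigen(targetCorr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("targetCorr must be positive semidefinite")
  if (is.null(dim(varRanges)))
    varRanges <- matrix(varRanges, p, 2, byrow = TRUE)
  Z <- vapply(seq_len(p), function(k) {
    f <- matrix(stats::rnorm(nRows * nCols), nRows, nCols)
    f <- .smoothDim(.smoothDim(f, autocorrLength, FALSE), autocorrLength, TRUE)
    as.vector((f - mean(f)) / stats::sd(f))
  }, numeric(nRows * nCols))
  U <- chol(targetCorr + diag(1e-10, p))
  V <- Z %*% U
  grids <- lapply(seq_len(p), function(k) {
    v <- V[, k]
    lo <- varRanges[k, 1]; hi <- varRanges[k, 2]
    v <- lo + (v - min(v)) / (max(v) - min(v)) * (hi - lo)
    matrix(v, nRows, nCols)
  })
  names(grids) <- variables
  mask <- matrix(TRUE, nRows, nCols)
  if (maskFraction > 0) {
    nbad <- floor(maskFraction * nRows * nCols)
    bad <- sample(nRows * nCols, nbad)
    mask[bad] <- FALSE
    grids <- lapply(grids, function(g) { g[bad] <- NA_real_; g })
  }
  new("EnvStack", grids = grids, xll = xll, yll = yll,
      cellsize = cellsize, mask = mask)
}

#' Simulate a pure-birth ultrametric tree
#'
#' Forward Yule process: with k extant lineages the waiting time to the
#' next split is Exponential(k * birthRate); the splitting lineage is drawn
#' uniformly.  After the n-th lineage appears the process runs for one more
#' Exponential(n * birthRate) interval, so the expected (unscaled) depth is
#' \eqn{\sum_{k=2}^{n} 1/(k \lambda)}.  By default the tree is rescaled to
#' depth 1 (relative time); the unscaled depth is kept in
#' \code{attr(tree, "rawDepth")}.
#'
#' @param nTips number of tips (>= 2)
#' @param birthRate speciation rate of the Yule process
#' @param seed integer seed
#' @param rescale rescale branch lengths so the depth is exactly 1
#' @return an ultrametric, rooted, binary \code{phylo} with tips
#'   \code{t1..tn}
#' @export
simulateTree <- function(nTips, birthRate = 1, seed = NULL, rescale = TRUE) {
  stopifnot(nTips >= 2)
  if (!is.null(seed)) set.seed(seed)
  maxNodes <- 2L * nTips - 1L
  parent <- integer(maxNodes); splitTime <- rep(NA_real_, maxNodes)
  splitTime[1] <- 0                       # root splits immediately at time 0
  parent[2:3] <- 1L
  active <- c(2L, 3L)
  nextId <- 4L
  t <- 0
  while (length(active) < nTips) {
    k <- length(active)
    t <- t + stats::rexp(1, k * birthRate)
    i <- active[sample.int(k, 1L)]
    splitTime[i] <- t
    parent[nextId + 0:1] <- i
    active <- c(active[active != i], nextId, nextId + 1L)
    nextId <- nextId + 2L
  }
  T <- t + stats::rexp(1, nTips * birthRate)
  isTip <- is.na(splitTime)
  tipIds <- which(isTip); intIds <- which(!isTip)
  map <- integer(maxNodes)
  map[tipIds] <- seq_len(nTips)
  map[intIds] <- nTips + seq_along(intIds)  # id 1 (root) maps to nTips + 1
  endTime <- ifelse(isTip, T, splitTime)
  children <- which(parent > 0L)
  edge <- cbind(map[parent[children]], map[children])
  edgeLength <- endTime[children] - splitTime[parent[children]]
  tr <- structure(list(edge = edge, edge.length = edgeLength,
                       tip.label = paste0("t", seq_len(nTips)),
                       Nnode = nTips - 1L),
                  class = "phylo", order = "cladewise")
  tr <- stats::reorder(tr, "cladewise")
  if (rescale) tr$edge.length <- tr$edge.length / T
  attr(tr, "rawDepth") <- T
  tr
}

.descendantTipSets <- function(tree) {
  n <- ape::Ntip(tree)
  res <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) res[[i]] <- i
  po <- stats::reorder(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    u <- po$edge[k, 1]; v <- po$edge[k, 2]
    res[[u]] <- c(res[[u]], res[[v]])
  }
  res
}

#' Partition tips into the k oldest clades
#'
#' Cuts the tree at a time point where exactly k lineages exist; each
#' lineage's descendant tips form one clade.  Used to emulate the "major
#' clade" structure of an empirical phylogeny on simulated trees.
#'
#' @param tree an ultrametric \code{phylo}
#' @param k number of clades (2 <= k <= nTips)
#' @return named character vector mapping tip label to clade
#'   (\code{"clade1"}..\code{"cladek"})
#' @export
cladesFromTree <- function(tree, k) {
  n <- ape::Ntip(tree)
  stopifnot(k >= 2, k <= n)
  depth <- checkUltrametric(tree)
  bt <- ape::branching.times(tree)
  nodeTime <- depth - bt                 # split times measured from the root
  splits <- sort(nodeTime)
  tCut <- if (k - 1L < length(splits))
    (splits[k - 1L] + splits[k]) / 2 else (splits[k - 1L] + depth) / 2
  tipSets <- .descendantTipSets(tree)
  allTime <- c(rep(depth, n), nodeTime[as.character(n + seq_len(tree$Nnode))])
  out <- character(n)
  cl <- 0L
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    if (allTime[u] < tCut && allTime[v] >= tCut) {
      cl <- cl + 1L
      out[tipSets[[v]]] <- paste0("clade", cl)
    }
  }
  names(out) <- tree$tip.label
  out
}

#' Evolve niche optima along a tree
#'
#' Optima evolve from the root values along every branch.  Under Brownian
#' motion the increment on a branch of length t is Normal(0, rateBM * t);
#' under Ornstein-Uhlenbeck the exact transition
#' \eqn{x_c \sim N(\theta + (x_p - \theta) e^{-\alpha t},
#' rateBM (1 - e^{-2\alpha t}) / (2\alpha))} is used, with the attractor
#' \eqn{\theta} set to the value at the clade's root (MRCA).  Regimes are
#' assigned per clade; branches above a clade's MRCA (the backbone) always
#' evolve under BM.  Niche breadths are inherited unchanged.
#'
#' @param tree a \code{phylo}
#' @param rootOptima named numeric, root optimum per variable
#' @param breadth named numeric, niche breadth (suitability SD) per variable
#' @param rateBM BM rate (variable units squared per unit branch length)
#' @param regimes named character clade -> "BM" or "OU" (NULL = all BM)
#' @param clades named character tip -> clade (required with regimes)
#' @param alpha OU mean-reversion strength (per unit branch length)
#' @param seed integer seed
#' @return list with \code{optima} (tips x variables), \code{breadth},
#'   \code{nodeOptima} (all nodes x variables, ape node order)
#' @export
evolveNiches <- function(tree, rootOptima, breadth, rateBM,
                         regimes = NULL, clades = NULL, alpha = 10,
                         seed = NULL) {
  stopifnot(rateBM >= 0, alpha >= 0, all(breadth > 0))
  if (!is.null(seed)) set.seed(seed)
  vars <- names(rootOptima)
  if (is.null(vars) || !setequal(vars, names(breadth)))
    stop("rootOptima and breadth must be named by the same variables")
  tree <- stats::reorder(tree, "cladewise")
  n <- ape::Ntip(tree)
  ntot <- n + tree$Nnode
  # nodeClade[v]: the clade if all tips below v belong to one clade, else NA
  tipSets <- .descendantTipSets(tree)
  nodeClade <- rep(NA_character_, ntot)
  if (!is.null(regimes)) {
    if (is.null(clades)) stop("clades are required when regimes are given")
    cl <- clades[tree$tip.label]
    for (v in seq_len(ntot)) {
      cc <- unique(cl[tipSets[[v]]])
      if (length(cc) == 1L) nodeClade[v] <- cc
    }
  }
  X <- matrix(NA_real_, ntot, length(vars), dimnames = list(NULL, vars))
  X[n + 1L, ] <- rootOptima[vars]
  theta <- list()
  if (!is.na(nodeClade[n + 1L]))        # whole tree is one clade: root is its MRCA
    theta[[nodeClade[n + 1L]]] <- X[n + 1L, ]
  for (k in seq_len(nrow(tree$edge))) {
    u <- tree$edge[k, 1]; v <- tree$edge[k, 2]
    len <- tree$edge.length[k]
    cladeU <- nodeClade[u]
    useOU <- !is.na(cladeU) && !is.null(regimes) &&
      identical(unname(regimes[cladeU]), "OU")
    if (useOU) {
      th <- theta[[cladeU]]
      decay <- exp(-alpha * len)
      sd <- sqrt(rateBM * (1 - exp(-2 * alpha * len)) / (2 * alpha))
      X[v, ] <- th + (X[u, ] - th) * decay + stats::rnorm(length(vars), 0, sd)
    } else {
      X[v, ] <- X[u, ] + stats::rnorm(length(vars), 0, sqrt(rateBM * len))
    }
    # entering a clade: the child (the clade MRCA) sets that clade's attractor
    if (!is.na(nodeClade[v]) && is.na(cladeU) &&
        is.null(theta[[nodeClade[v]]]))
      theta[[nodeClade[v]]] <- X[v, ]
  }
  optima <- X[seq_len(n), , drop = FALSE]
  rownames(optima) <- tree$tip.label
  list(optima = optima, breadth = breadth[vars], nodeOptima = X)
}

#' True (generator) suitability surface
#'
#' Gaussian niche response per variable, multiplied across variables:
#' \eqn{s(cell) = \exp(-\sum_k (e_k - \mu_k)^2 / (2 \sigma_k^2))}.  This is
#' the analytic truth against which fitted models can be compared.
#'
#' @param stack an [EnvStack-class]
#' @param optima named numeric, niche optimum per variable
#' @param breadth named numeric, niche breadth per variable
#' @return numeric vector of suitabilities over the non-masked cells (in
#'   [envValues()] order), not normalized
#' @export
trueSuitability <- function(stack, optima, breadth) {
  vars <- names(optima)
  E <- envValues(stack, vars)
  q <- rowSums(sweep(sweep(E, 2L, optima[vars])^2, 2L,
                     2 * breadth[vars]^2, `/`))
  exp(-q)
}

#' Sample occurrence points proportional to suitability
#'
#' Cells are drawn with probability proportional to the true suitability;
#' each point is then placed uniformly within its cell.
#'
#' @param stack an [EnvStack-class]
#' @param optima,breadth niche parameters (see [trueSuitability()])
#' @param n number of points (>= 0)
#' @param species species name for the returned set
#' @param seed integer seed
#' @return an [OccurrenceSet-class]
#' @export
sampleOccurrences <- function(stack, optima, breadth, n,
                              species = "sp", seed = NULL) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  s <- trueSuitability(stack, optima, breadth)
  if (sum(s) <= 0 || !any(s > 0))
    stop("species '", species, "': suitability is zero everywhere")
  centers <- envCellCenters(stack)
  pick <- sample.int(length(s), n, replace = TRUE, prob = s)
  cs <- stack@cellsize
  pts <- cbind(x = centers[pick, 1] + stats::runif(n, -cs / 2, cs / 2),
               y = centers[pick, 2] + stats::runif(n, -cs / 2, cs / 2))
  new("OccurrenceSet", species = species, points = pts,
      source = "synthetic")
}

#' Generate a complete synthetic study
#'
#' Bundles the four generators into one reproducible dataset emulating the
#' inputs of a phyloclimatic analysis: correlated environmental layers, an
#' ultrametric phylogeny partitioned into major clades, per-species niche
#' optima evolved under the per-clade regimes, and occurrence samples drawn
#' from the true suitability surfaces.  Every stage uses a seed derived
#' from the master seed via [deriveSeed()].
#'
#' @param nSpecies number of species (tree tips)
#' @param nClades number of major clades (see [cladesFromTree()])
#' @param regimes character of length nClades, "BM" or "OU" per clade
#' @param variables environmental variable names
#' @param nRows,nCols,autocorrLength,targetCorr,varRanges passed to
#'   [simulateEnvStack()]
#' @param birthRate Yule speciation rate
#' @param rootOptima,breadth,rateBM,alpha passed to [evolveNiches()]
#'   (defaults: mid-range optima, breadth 12, rateBM 900, alpha 10 on a
#'   0--100 variable scale and depth-1 tree)
#' @param nOcc occurrence points per species
#' @param seed master seed
#' @return list with \code{stack}, \code{tree}, \code{clades},
#'   \code{regimes}, \code{occurrences} (named list) and \code{truth}
#'   (optima, breadth, nodeOptima)
#' @export
simulateDataset <- function(nSpecies = 12, nClades = 3,
                            regimes = rep("BM", nClades),
                            variables = c("env1", "env2", "env3"),
                            nRows = 30, nCols = nRows, autocorrLength = 3,
                            targetCorr = 0.4, varRanges = c(0, 100),
                            birthRate = 1,
                            rootOptima = NULL, breadth = NULL,
                            rateBM = 900, alpha = 10,
                            nOcc = 30, seed = 1) {
  stack <- simulateEnvStack(variables, nRows, nCols, autocorrLength,
                            targetCorr, varRanges,
                            seed = deriveSeed(seed, "env"))
  tree <- simulateTree(nSpecies, birthRate, seed = deriveSeed(seed, "tree"))
  clades <- cladesFromTree(tree, nClades)
  names(regimes) <- paste0("clade", seq_len(nClades))
  if (is.null(rootOptima)) {
    E <- envValues(stack)
    rootOptima <- (apply(E, 2L, min) + apply(E, 2L, max)) / 2
  }
  if (is.null(breadth))
    breadth <- stats::setNames(rep(12, length(variables)), variables)
  truth <- evolveNiches(tree, rootOptima, breadth, rateBM,
                        regimes = regimes, clades = clades, alpha = alpha,
                        seed = deriveSeed(seed, "niches"))
  occ <- lapply(tree$tip.label, function(sp)
    sampleOccurrences(stack, truth$optima[sp, ], truth$breadth, nOcc,
                      species = sp, seed = deriveSeed(seed, paste0("occ:", sp))))
  names(occ) <- tree$tip.label
  list(stack = stack, tree = tree, clades = clades, regimes = regimes,
       occurrences = occ, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Emits the study in the external formats the pipeline reads back: one
#' .asc per variable, \code{occurrences.csv}, \code{tree.nwk},
#' \code{clades.csv}, and a \code{truth.csv} with the per-tip generator
#' parameters for parameter-recovery checks.
#'
#' @param dataset result of [simulateDataset()]
#' @param dir output directory
#' @return invisibly, \code{dir}
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeEnvStack(dataset$stack, dir)
  writeOccurrences(dataset$occurrences, file.path(dir, "occurrences.csv"))
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(data.frame(species = names(dataset$clades),
                              clade = unname(dataset$clades)),
                   file.path(dir, "clades.csv"), row.names = FALSE)
  tv <- dataset$truth$optima
  truth <- data.frame(species = rownames(tv),
                      clade = unname(dataset$clades[rownames(tv)]),
                      regime = unname(dataset$regimes[dataset$clades[rownames(tv)]]))
  for (v in colnames(tv)) {
    truth[[paste0("mu_", v)]] <- tv[, v]
    truth[[paste0("sigma_", v)]] <- dataset$truth$breadth[v]
  }
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
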