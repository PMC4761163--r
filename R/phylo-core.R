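# Phylogenetic numerics shared by the niche-evolution stages: phylogenetic
# covariance, maximum-likelihood Brownian ancestral states (GLS), and BM
# trait simulation.  Trees are ape "phylo" objects throughout.

#' Check that a tree is ultrametric within tolerance
#'
#' @param tree a rooted, binary \code{phylo} with branch lengths
#' @param tol relative tolerance on tip depths (fraction of tree depth)
#' @return invisibly, the tree depth
#' @export
checkUltrametric <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  depth <- max(depths)
  if (depth <= 0) stop("tree has zero depth")
  if (diff(range(depths)) > tol * depth)
    stop("tree is not ultrametric within tolerance ", tol)
  invisible(depth)
}

#' Phylogenetic covariance matrix
#'
#' C[i, j] is the shared path length from the root for tips i and j; for an
#' ultrametric tree the diagonal equals the tree depth.  This is the trait
#' covariance (up to the rate) under Brownian motion and underlies the GLS
#' ancestral states, the phylogenetic PCA and the MANOVA null.
#'
#' @param tree a \code{phylo}
#' @return symmetric positive-definite matrix with tip-label dimnames
#' @export
phyloCovariance <- function(tree) ape::vcv.phylo(tree)

# Weighted graph Laplacian of the tree with edge weights 1/length; rows and
# columns indexed by ape node ids (tips first).
.treeLaplacian <- function(tree) {
  if (any(tree$edge.length <= 0))
    stop("non-positive branch length: BM system is singular")
  ntot <- ape::Ntip(tree) + tree$Nnode
  L <- matrix(0, ntot, ntot)
  w <- 1 / tree$edge.length
  for (k in seq_len(nrow(tree$edge))) {
    u <- tree$edge[k, 1]; v <- tree$edge[k, 2]
    L[u, u] <- L[u, u] + w[k]; L[v, v] <- L[v, v] + w[k]
    L[u, v] <- L[u, v] - w[k]; L[v, u] <- L[v, u] - w[k]
  }
  L
}

# Linear operator A such that internal-node GLS states = A %*% tipValues.
.ancestralOperator <- function(tree) {
  n <- ape::Ntip(tree)
  L <- .treeLaplacian(tree)
  int <- n + seq_len(tree$Nnode)
  tip <- seq_len(n)
  A <- -solve(L[int, int, drop = FALSE], L[int, tip, drop = FALSE])
  colnames(A) <- tree$tip.label
  rownames(A) <- as.character(int)
  A
}

#' Maximum-likelihood Brownian-motion ancestral states
#'
#' Returns the internal-node values that maximize the BM likelihood given
#' the tip values, equivalently the minimizer of
#' \eqn{\sum_{edges} (\Delta x)^2 / length} (the GLS solution).  The root
#' estimate equals \eqn{(1' C^{-1} 1)^{-1} 1' C^{-1} x}.  Reconstruction is
#' linear in the tip values.
#'
#' @param tree a rooted \code{phylo} with positive branch lengths
#' @param tipValues numeric vector named by tip label (or in tip order)
#' @return numeric vector of internal-node values named by ape node id
#'   (root first)
#' @export
bmAncestralStates <- function(tree, tipValues) {
  n <- ape::Ntip(tree)
  if (!is.null(names(tipValues))) {
    if (!setequal(names(tipValues), tree$tip.label))
      stop("tipValues names must match the tree's tip labels")
    tipValues <- tipValues[tree$tip.label]
  }
  if (length(tipValues) != n || any(!is.finite(tipValues)))
    stop("need one finite value per tip")
  A <- .ancestralOperator(tree)
  drop(A %*% tipValues)
}

#' Simulate traits under Brownian motion on a tree
#'
#' Each edge receives an independent Normal(0, rate * length) increment.
#'
#' @param tree a \code{phylo}
#' @param rootValue trait value at the root
#' @param rate BM rate (variance per unit branch length, >= 0)
#' @param nSims number of independent replicate simulations
#' @param seed optional integer seed
#' @return matrix (tips x nSims) with tip-label rownames
#' @export
bmSimulate <- function(tree, rootValue = 0, rate = 1, nSims = 1, seed = NULL) {
  stopifnot(rate >= 0, nSims >= 1)
  if (!is.null(seed)) set.seed(seed)
  tree <- stats::reorder(tree, "cladewise")
  n <- ape::Ntip(tree)
  ntot <- n + tree$Nnode
  vals <- matrix(0, ntot, nSims)
  vals[n + 1L, ] <- rootValue
  for (k in seq_len(nrow(tree$edge))) {
    u <- tree$edge[k, 1]; v <- tree$edge[k, 2]
    vals[v, ] <- vals[u, ] + stats::rnorm(nSims, 0, sqrt(rate * tree$edge.length[k]))
  }
  out <- vals[seq_len(n), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' GLS estimate of the Brownian-motion rate
#'
#' Phylogenetically corrected variance of the tip values:
#' \eqn{(x - \hat a 1)' C^{-1} (x - \hat a 1) / (n - 1)} with \eqn{\hat a}
#' the GLS phylogenetic mean.  Used as the rate of the null simulations in
#' [mdi()].
#'
#' @param tree a \code{phylo}
#' @param tipValues numeric vector named by tip label (or in tip order)
#' @return list with \code{rate} and phylogenetic mean \code{mean}
#' @export
bmRate <- function(tree, tipValues) {
  if (!is.null(names(tipValues))) tipValues <- tipValues[tree$tip.label]
  C <- phyloCovariance(tree)
  Ci <- solve(C)
  one <- rep(1, nrow(C))
  a <- drop(crossprod(one, Ci %*% tipValues) / crossprod(one, Ci %*% one))
  r <- tipValues - a
  list(rate = drop(crossprod(r, Ci %*% r)) / (length(tipValues) - 1), mean = a)
}
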