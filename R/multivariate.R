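# Phylogenetic PCA of PNO weighted means and phylogenetic MANOVA against a
# Brownian-simulation null.

.glsMeanCov <- function(C, X) {
  Ci <- solve(C)
  one <- rep(1, nrow(X))
  a <- drop(crossprod(one, Ci %*% X) / drop(crossprod(one, Ci %*% one)))
  Xc <- sweep(X, 2L, a)
  R <- crossprod(Xc, Ci %*% Xc) / (nrow(X) - 1)
  list(a = a, Xc = Xc, R = R)
}

#' Phylogenetic principal components analysis
#'
#' PCA on the evolutionary (phylogenetically corrected) covariance matrix:
#' the phylogenetic mean is the GLS estimate
#' \eqn{a = (1'C^{-1}1)^{-1} 1'C^{-1}X}, the evolutionary covariance
#' \eqn{R = (X - 1a')' C^{-1} (X - 1a') / (N - 1)} is eigendecomposed, and
#' scores are the centered data projected on the eigenvectors.  With
#' \code{mode = "corr"} (the default, appropriate when variables carry
#' different units) each variable is scaled by its evolutionary standard
#' deviation, i.e. the decomposition uses the evolutionary correlation
#' matrix.  On a star phylogeny \code{mode = "cov"} reduces to ordinary
#' covariance PCA.
#'
#' @param tree a \code{phylo}
#' @param X numeric matrix, species x variables, rownames = tip labels;
#'   near-constant variables should be excluded upstream
#' @param mode "corr" (unit evolutionary variance scaling) or "cov"
#' @return a [PPCAResult-class]
#' @export
phyloPCA <- function(tree, X, mode = c("corr", "cov")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- tree$tip.label
  C <- phyloCovariance(tree)[rownames(X), rownames(X)]
  g <- .glsMeanCov(C, X)
  Xc <- g$Xc
  R <- g$R
  if (mode == "corr") {
    sdv <- sqrt(diag(R))
    if (any(sdv == 0)) stop("zero evolutionary variance; exclude constant variables")
    Xc <- sweep(Xc, 2L, sdv, `/`)
    R <- R / tcrossprod(sdv)
  }
  e <- eigen(R, symmetric = TRUE)
  V <- e$vectors
  dimnames(V) <- list(colnames(X), paste0("PC", seq_len(ncol(V))))
  scores <- Xc %*% V
  new("PPCAResult", mean = g$a, evolCov = g$R, values = pmax(e$values, 0),
      vectors = V, scores = scores,
      varExplained = pmax(e$values, 0) / sum(pmax(e$values, 0)), mode = mode)
}

#' Wilks' Lambda and its exact-F transform
#'
#' One-way MANOVA statistic from ordinary within/between SSCP matrices,
#' converted to an F statistic by Rao's transform (exact for two groups,
#' where the degrees of freedom are \code{(p, N - p - 1)}).
#'
#' @param X numeric matrix, observations x responses
#' @param groups factor of group labels
#' @return list with \code{lambda}, \code{F}, \code{df1}, \code{df2}
#' @export
wilksF <- function(X, groups) {
  X <- as.matrix(X)
  groups <- droplevels(as.factor(groups))
  N <- nrow(X); p <- ncol(X); g <- nlevels(groups)
  if (g < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("every group needs at least two observations")
  if (p >= N - g + 1L) stop("too many responses for the group sizes")
  tot <- sweep(X, 2L, colMeans(X))
  T <- crossprod(tot)
  W <- matrix(0, p, p)
  for (lev in levels(groups)) {
    Xi <- X[groups == lev, , drop = FALSE]
    W <- W + crossprod(sweep(Xi, 2L, colMeans(Xi)))
  }
  lambda <- det(W) / det(T)
  t <- if (p^2 + (g - 1)^2 - 5 > 0)
    sqrt((p^2 * (g - 1)^2 - 4) / (p^2 + (g - 1)^2 - 5)) else 1
  df1 <- p * (g - 1)
  df2 <- ((N - 1) - (p + g) / 2) * t - (p * (g - 1) - 2) / 2
  lroot <- lambda^(1 / t)
  list(lambda = lambda, F = (1 - lroot) / lroot * df2 / df1,
       df1 = df1, df2 = df2)
}

#' Phylogenetic MANOVA
#'
#' Tests a grouping factor (e.g. position relative to a biogeographic
#' barrier) on multivariate trait data while accounting for phylogeny: the
#' observed Wilks/F statistic is computed as in an ordinary one-way MANOVA,
#' and its null distribution is generated by simulating the responses under
#' multivariate Brownian motion on the tree (rate matrix = GLS estimate
#' from the data) with the group labels held fixed.  The p-value is
#' \eqn{(1 + \#\{F_{sim} \ge F_{obs}\}) / (nSims + 1)} and is invariant to
#' relabeling the groups.
#'
#' @param tree a \code{phylo}
#' @param X numeric matrix, species x responses (e.g. the first
#'   phylogenetic principal components), rownames = tip labels
#' @param groups factor (or named vector) of group labels, each level with
#'   at least two species
#' @param nSims Brownian simulations (default 1000)
#' @param seed integer seed
#' @return a [PhyloMANOVAResult-class]
#' @export
phyloMANOVA <- function(tree, X, groups, nSims = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- tree$tip.label
  if (!is.null(names(groups))) groups <- groups[rownames(X)]
  groups <- droplevels(as.factor(groups))
  obs <- wilksF(X, groups)
  C <- phyloCovariance(tree)[rownames(X), rownames(X)]
  R <- .glsMeanCov(C, X)$R
  cholC <- chol(C)
  cholR <- chol(R + diag(1e-12 * max(diag(R)), ncol(R)))
  N <- nrow(X); p <- ncol(X)
  nullF <- vapply(seq_len(nSims), function(s) {
    Xs <- crossprod(cholC, matrix(stats::rnorm(N * p), N, p)) %*% cholR
    wilksF(Xs, groups)$F
  }, numeric(1))
  new("PhyloMANOVAResult", wilks = obs$lambda, F = obs$F,
      df1 = obs$df1, df2 = obs$df2,
      pValue = (1 + sum(nullF >= obs$F)) / (nSims + 1),
      nullF = nullF, nSims = nSims, groups = groups)
}
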