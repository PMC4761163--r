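# Independent oracles shared by the unit and acceptance suites.

# Brute-force BM ancestral states: minimize sum over edges of (dx)^2/length
# by direct numerical optimization (BFGS with analytic gradient, then one
# exact Newton step -- the objective is quadratic, so a finite-difference
# Hessian of the gradient is exact and the step lands on the minimizer).
# Nothing is shared with the package's linear solve.
bruteForceAncestral <- function(tree, tipValues) {
  n <- ape::Ntip(tree)
  tipValues <- tipValues[tree$tip.label]
  obj <- function(z) {
    x <- c(tipValues, z)
    sum((x[tree$edge[, 1]] - x[tree$edge[, 2]])^2 / tree$edge.length)
  }
  grad <- function(z) {
    x <- c(tipValues, z)
    g <- numeric(length(x))
    d <- 2 * (x[tree$edge[, 1]] - x[tree$edge[, 2]]) / tree$edge.length
    for (k in seq_along(d)) {
      g[tree$edge[k, 1]] <- g[tree$edge[k, 1]] + d[k]
      g[tree$edge[k, 2]] <- g[tree$edge[k, 2]] - d[k]
    }
    g[-seq_len(n)]
  }
  par <- optim(rep(mean(tipValues), tree$Nnode), obj, grad, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))$par
  m <- length(par)
  g0 <- grad(par)
  H <- vapply(seq_len(m), function(j) {
    e <- numeric(m); e[j] <- 1
    grad(par + e) - g0
  }, numeric(m))
  par <- par - solve(H, g0)
  setNames(par, n + seq_len(tree$Nnode))
}

# Constrained maximum-entropy oracle: maximize H(p) subject to
# E_p[f_j] = b_j over the probability simplex.  Solved through the smooth
# convex Lagrange-dual min_l log sum_i exp(f_i . l) - l . b (whose unique
# stationary point recovers the constrained-entropy maximizer) with BFGS
# followed by exact Newton polish -- algorithmically unrelated to the
# package's cyclic soft-threshold coordinate descent.  F is the cells x
# features matrix, b the target feature means.
maxentEntropyOracle <- function(F, b) {
  toP <- function(l) {
    e <- drop(F %*% l)
    p <- exp(e - max(e))
    p / sum(p)
  }
  dual <- function(l) {
    e <- drop(F %*% l)
    m <- max(e)
    m + log(sum(exp(e - m))) - sum(l * b)
  }
  dgrad <- function(l) colSums(F * toP(l)) - b
  l <- optim(numeric(ncol(F)), dual, dgrad, method = "BFGS",
             control = list(maxit = 10000, reltol = 1e-14))$par
  for (it in 1:50) {                     # Newton: H = feature covariance under p
    p <- toP(l)
    g <- colSums(F * p) - b
    if (max(abs(g)) < 1e-12) break
    mu <- colSums(F * p)
    H <- crossprod(F * sqrt(p)) - tcrossprod(mu)
    step <- tryCatch(solve(H + diag(1e-12, ncol(F)), g), error = function(e) g)
    l <- l - step
  }
  toP(l)
}
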