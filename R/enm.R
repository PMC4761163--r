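# Maximum-entropy niche models with linear + quadratic features.
#
# The fitted model is the Gibbs distribution p(i) ~ exp(lambda . f(i)) over
# the non-masked grid cells minimizing the L1-penalized negative
# log-likelihood of the presences,
#   J(lambda) = log Z(lambda) - lambda . fbar + sum_j beta_j |lambda_j|,
# with fbar the presence mean of the standardized features and
# beta_j = beta * sd_presence(f_j) / sqrt(m).  The program is convex; it is
# solved by cyclic coordinate descent with a soft-threshold Newton step and
# per-update backtracking, so the objective trace is non-increasing.  At the
# optimum the KKT conditions bound |E_p[f_j] - fbar_j| by beta_j.

# Standardized linear + quadratic feature matrix; centers/scales come from
# the background so models on different occurrence sets share one feature
# space.
.featureMatrix <- function(E, center, scale,
                           features = c("linear", "quadratic")) {
  Z <- sweep(sweep(E, 2L, center), 2L, scale, `/`)
  out <- NULL
  if ("linear" %in% features) {
    lin <- Z
    colnames(lin) <- paste0(colnames(E), ".lin")
    out <- cbind(out, lin)
  }
  if ("quadratic" %in% features) {
    quad <- Z^2
    colnames(quad) <- paste0(colnames(E), ".quad")
    out <- cbind(out, quad)
  }
  if (is.null(out)) out <- matrix(0, nrow(E), 0L)
  out
}

.gibbs <- function(eta) {
  m <- max(eta)
  e <- exp(eta - m)
  Z <- sum(e)
  list(p = e / Z, logZ = m + log(Z))
}

#' Fit a maximum-entropy niche model
#'
#' Presence-only Gibbs model over the stack's non-masked cells with
#' standardized linear and quadratic features of each environmental
#' variable, L1-regularized with per-feature penalties
#' \code{beta * sd_presence(f_j) / sqrt(m)}.  Species with fewer than
#' \code{minOccurrences} records are refused (they are excluded from niche
#' analyses), mirroring standard ENM practice for narrow endemics.
#'
#' The raw output is the fitted cell distribution (sums to 1); the logistic
#' output is \code{tau * e^H * p_i / (1 - tau + tau * e^H * p_i)} with H the
#' entropy of the raw distribution and prevalence \code{tau} (default 0.5),
#' so a featureless model has logistic value \code{tau} everywhere.
#'
#' @param stack an [EnvStack-class]
#' @param occ an [OccurrenceSet-class]; all points must fall on non-masked
#'   cells
#' @param beta regularization multiplier (default 1)
#' @param maxIter maximum coordinate-descent sweeps (default 1000)
#' @param tol convergence threshold on the objective change per sweep
#' @param features feature classes to use (subset of "linear", "quadratic";
#'   empty gives the uniform maximum-entropy model)
#' @param tau logistic prevalence
#' @param minOccurrences modeling minimum (default 5)
#' @return a [NicheModel-class]
#' @export
fitMaxent <- function(stack, occ, beta = 1, maxIter = 1000, tol = 1e-6,
                      features = c("linear", "quadratic"), tau = 0.5,
                      minOccurrences = 5) {
  if (nOcc(occ) < minOccurrences) {
    cond <- simpleError(sprintf(
      "species '%s' has %d occurrence(s) (< %d): excluded from niche analyses",
      occ@species, nOcc(occ), minOccurrences))
    class(cond) <- c("enmTooFewOccurrences", class(cond))
    stop(cond)
  }
  idx <- validateOccurrences(occ, stack)
  maskIdx <- which(stack@mask)
  pos <- match(idx, maskIdx)
  E <- envValues(stack)
  center <- colMeans(E)
  scale <- apply(E, 2L, stats::sd)
  scale[scale == 0] <- 1
  F <- .featureMatrix(E, center, scale, features)
  nf <- ncol(F)
  m <- length(pos)
  Fp <- F[pos, , drop = FALSE]
  b <- colMeans(Fp)
  sj <- if (m > 1) apply(Fp, 2L, stats::sd) else rep(0, nf)
  betaJ <- beta * sj / sqrt(m)
  lambda <- numeric(nf)
  names(lambda) <- names(betaJ) <- colnames(F)
  eta <- numeric(nrow(F))
  g <- .gibbs(eta)
  objective <- g$logZ - sum(lambda * b) + sum(betaJ * abs(lambda))
  trace <- objective
  converged <- nf == 0L
  iter <- 0L
  while (!converged && iter < maxIter) {
    iter <- iter + 1L
    prev <- objective
    for (j in seq_len(nf)) {
      fj <- F[, j]
      mu <- sum(g$p * fj)
      grad <- mu - b[j]
      hess <- sum(g$p * fj^2) - mu^2
      if (hess < 1e-12) next
      z <- hess * lambda[j] - grad
      lnew <- sign(z) * max(abs(z) - betaJ[j], 0) / hess
      delta <- lnew - lambda[j]
      if (delta == 0) next
      # backtrack on the true objective so the trace is monotone
      for (try in 1:25) {
        etaNew <- eta + delta * fj
        gNew <- .gibbs(etaNew)
        lamJ <- lambda[j] + delta
        objNew <- gNew$logZ - sum(lambda * b) - delta * b[j] +
          sum(betaJ * abs(lambda)) - betaJ[j] * abs(lambda[j]) +
          betaJ[j] * abs(lamJ)
        if (objNew <= objective + 1e-12) break
        delta <- delta / 2
      }
      if (objNew <= objective + 1e-12) {
        lambda[j] <- lambda[j] + delta
        eta <- etaNew
        g <- gNew
        objective <- objNew
      }
    }
    trace <- c(trace, objective)
    if (abs(prev - objective) < tol) converged <- TRUE
  }
  if (!converged)
    warning("species '", occ@species, "': optimizer reached maxIter = ",
            maxIter, " without converging")
  p <- g$p
  H <- -sum(p[p > 0] * log(p[p > 0]))
  expH <- exp(H + log(p))
  logistic <- tau * expH / (1 - tau + tau * expH)
  rawM <- logM <- matrix(NA_real_, nrow(stack@mask), ncol(stack@mask))
  rawM[maskIdx] <- p
  logM[maskIdx] <- logistic
  new("NicheModel", species = occ@species, variables = envVariables(stack),
      lambda = lambda, beta = beta, betaJ = betaJ,
      featureCenter = center, featureScale = scale,
      raw = rawM, logistic = logM, entropy = H, tau = tau,
      mtp = min(logistic[pos]), converged = converged,
      nIter = iter, objective = trace)
}

#' Rank-based AUC for presence vs background scores
#'
#' Mann-Whitney statistic: the probability that a random presence outscores
#' a random background cell, ties counting one half.
#'
#' @param presence,background numeric score vectors
#' @return AUC in \code{[0, 1]}
#' @export
rankAUC <- function(presence, background) {
  np <- length(presence); nb <- length(background)
  if (np == 0L || nb == 0L) stop("need non-empty presence and background scores")
  r <- rank(c(presence, background))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Evaluate a niche model by replicate subsampling
#'
#' For each replicate, the occurrences are split into a training fraction
#' and a test remainder, a model is fitted on the training points, and the
#' test presences are scored against all non-masked background cells with
#' the rank AUC.  The report passes when the mean AUC reaches the gate.
#'
#' @param stack an [EnvStack-class]
#' @param occ an [OccurrenceSet-class]
#' @param nReplicates number of random splits (default 10)
#' @param trainFrac training fraction (default 0.59)
#' @param gate mean-AUC pass threshold (default 0.7)
#' @param seed integer seed
#' @param ... passed to [fitMaxent()]
#' @return list with \code{replicates} (data frame of per-replicate AUC),
#'   \code{meanAUC}, \code{pass}
#' @export
evaluateAUC <- function(stack, occ, nReplicates = 10, trainFrac = 0.59,
                        gate = 0.7, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- nOcc(occ)
  nTrain <- round(trainFrac * n)
  if (nTrain < 1L || nTrain >= n)
    stop("too few occurrences to split into training and test sets")
  auc <- numeric(nReplicates)
  splits <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    tr <- sort(sample.int(n, nTrain))
    splits[[r]] <- tr
    occTr <- methods::initialize(occ, points = occ@points[tr, , drop = FALSE])
    occTe <- methods::initialize(occ, points = occ@points[-tr, , drop = FALSE])
    fit <- fitMaxent(stack, occTr, ...)
    sc <- fit@logistic[which(stack@mask)]
    posTe <- match(cellIndexOf(stack, occTe@points), which(stack@mask))
    auc[r] <- rankAUC(sc[posTe], sc)
  }
  list(replicates = data.frame(replicate = seq_len(nReplicates), auc = auc),
       splits = splits, meanAUC = mean(auc), pass = mean(auc) >= gate)
}

#' Apply the minimum-training-presence threshold
#'
#' A cell is suitable iff its logistic value is at least the lowest
#' logistic value observed at a training presence.  By default the
#' threshold stored in the model (from its training points) is used; pass
#' \code{occ} together with \code{stack} to recompute it from other points.
#'
#' @param model a [NicheModel-class]
#' @param occ optional [OccurrenceSet-class] defining the threshold
#' @param stack required with \code{occ}
#' @return logical matrix (NA on masked cells)
#' @export
applyMTP <- function(model, occ = NULL, stack = NULL) {
  thr <- model@mtp
  if (!is.null(occ)) {
    if (is.null(stack)) stop("stack is required to locate the occurrences")
    idx <- validateOccurrences(occ, stack)
    thr <- min(model@logistic[idx])
  }
  model@logistic >= thr
}

#' Cumulative clade suitability map
#'
#' Per-cell sum of the logistic surfaces of a clade's species models, as
#' used for cumulative-suitability maps; with k models the result is
#' bounded by k.
#'
#' @param models list of [NicheModel-class] fitted on one stack
#' @return numeric matrix (NA on masked cells)
#' @export
cumulativeCladeMap <- function(models) {
  if (length(models) == 0L) stop("no models given")
  d <- dim(models[[1]]@logistic)
  for (m in models)
    if (!identical(dim(m@logistic), d))
      stop("models were fitted on different grids")
  Reduce(`+`, lapply(models, methods::slot, "logistic"))
}
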