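# Age-range correlation: regression of per-node cross-clade niche overlap
# on node age, with per-node intervals and a permutation test for the
# slope.

#' Per-node cross-clade overlap
#'
#' Summarizes each internal node n by the weighted mean of overlap(i, j)
#' over the tip pairs whose MRCA is n.  With \code{weighting = "ft"} a pair
#' is down-weighted by \eqn{0.5^k}, k the number of internal nodes on the
#' i--j path excluding n (nested pairs count less); \code{"mean"} is the
#' unweighted average of the cross-clade pairs.
#'
#' @param tree a \code{phylo}
#' @param M symmetric overlap matrix with tip-label dimnames (or an
#'   [OverlapMatrix-class])
#' @param weighting "ft" or "mean"
#' @param metric metric to extract when \code{M} is an OverlapMatrix
#' @return numeric vector of node overlaps named by ape node id
#' @export
arcNodeOverlaps <- function(tree, M, weighting = c("ft", "mean"),
                            metric = c("D", "I")) {
  weighting <- match.arg(weighting)
  if (methods::is(M, "OverlapMatrix")) M <- slot(M, match.arg(metric))
  .nodeOverlaps(tree, M, weighting)
}

.nodeOverlaps <- function(tree, M, weighting) {
  n <- ape::Ntip(tree)
  stopifnot(all(tree$tip.label %in% rownames(M)))
  M <- M[tree$tip.label, tree$tip.label]
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  # ancestors of each tip, bottom-up
  anc <- lapply(seq_len(n), function(i) {
    out <- integer(0)
    v <- i
    while (parent[v] != 0L) { v <- parent[v]; out <- c(out, v) }
    out
  })
  mrca <- ape::mrca(tree)
  o <- numeric(tree$Nnode)
  names(o) <- as.character(n + seq_len(tree$Nnode))
  w <- numeric(tree$Nnode)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    node <- mrca[i, j]
    k <- sum(anc[[i]] != node & !(anc[[i]] %in% anc[[j]])) +
         sum(anc[[j]] != node & !(anc[[j]] %in% anc[[i]]))
    wij <- if (weighting == "ft") 0.5^k else 1
    id <- node - n
    o[id] <- o[id] + wij * M[i, j]
    w[id] <- w[id] + wij
  }
  o / w
}

#' Age-range correlation of niche overlap
#'
#' Summarizes each internal node by the (weighted) mean overlap between the
#' tips on either side of the node and regresses that node overlap on node
#' age.  A negative slope indicates accumulation of niche differences with
#' divergence time.  Nodes falling outside their per-node 95 % interval
#' (prediction interval by default; mean-response confidence band via
#' \code{interval = "confidence"}) are flagged as exhibiting more
#' ("above") or less ("below") overlap than expected for their age.
#' Significance of the slope is assessed by permuting the tip identities of
#' the overlap matrix (two-sided; \code{nPermutations = 0} skips it).
#'
#' @param tree an ultrametric \code{phylo}
#' @param overlap an [OverlapMatrix-class] or symmetric overlap matrix with
#'   tip-label dimnames
#' @param metric "D" or "I" when \code{overlap} is an OverlapMatrix
#' @param weighting "ft" (nested pairs down-weighted 0.5 per intervening
#'   node) or "mean"
#' @param nPermutations permutation replicates for the slope p-value
#' @param conf level of the per-node interval
#' @param interval "prediction" or "confidence"
#' @param seed integer seed
#' @return an [ARCResult-class]
#' @export
ageRangeCorrelation <- function(tree, overlap, metric = c("D", "I"),
                                weighting = c("ft", "mean"),
                                nPermutations = 1000, conf = 0.95,
                                interval = c("prediction", "confidence"),
                                seed = NULL) {
  metric <- match.arg(metric)
  weighting <- match.arg(weighting)
  interval <- match.arg(interval)
  if (!is.null(seed)) set.seed(seed)
  M <- if (methods::is(overlap, "OverlapMatrix")) slot(overlap, metric) else overlap
  n <- ape::Ntip(tree)
  if (tree$Nnode < 3L)
    stop("need at least 3 internal nodes for the regression")
  age <- ape::branching.times(tree)
  o <- .nodeOverlaps(tree, M, weighting)
  d <- data.frame(age = age[names(o)], overlap = o)
  fit <- stats::lm(overlap ~ age, data = d)
  # prediction intervals at the observed nodes; predict.lm's "future
  # responses" caution is exactly the intended usage here
  pred <- suppressWarnings(stats::predict(fit, interval = interval, level = conf))
  flag <- ifelse(d$overlap > pred[, "upr"], "above",
                 ifelse(d$overlap < pred[, "lwr"], "below", ""))
  nodes <- data.frame(node = as.integer(names(o)), age = d$age,
                      overlap = d$overlap, fit = pred[, "fit"],
                      lwr = pred[, "lwr"], upr = pred[, "upr"], flag = flag)
  slope <- unname(stats::coef(fit)["age"])
  pValue <- NA_real_
  if (nPermutations > 0) {
    perms <- vapply(seq_len(nPermutations), function(s) {
      idx <- sample.int(nrow(M))
      Mp <- M[idx, idx]
      dimnames(Mp) <- dimnames(M)
      op <- .nodeOverlaps(tree, Mp, weighting)
      unname(stats::coef(stats::lm(op ~ d$age))[2])
    }, numeric(1))
    pValue <- (1 + sum(abs(perms) >= abs(slope))) / (nPermutations + 1)
  }
  new("ARCResult", nodes = nodes, slope = slope,
      intercept = unname(stats::coef(fit)[1]), pValue = pValue,
      weighting = weighting, metric = metric, conf = conf,
      interval = interval)
}
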