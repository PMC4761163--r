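# Predicted niche occupancy (PNO) profiles and Brownian-motion ancestral
# tolerance reconstruction.

#' Predicted niche occupancy profile
#'
#' Bins the model's suitability mass along one environmental variable: the
#' mass of a bin is the summed (normalized) suitability of the cells whose
#' variable value falls in the bin, so the profile is a probability
#' distribution over niche space (sums to 1).  Bin edges default to
#' \code{nBins} equal-width bins spanning the variable's range over the
#' non-masked cells, so profiles of different species are directly
#' comparable; pass \code{breaks} for explicit edges.  A constant variable
#' yields a degenerate single-bin profile, with a warning.
#'
#' @param model a [NicheModel-class], or a numeric suitability distribution
#'   over the non-masked cells (summing to 1)
#' @param stack the [EnvStack-class] the model was fitted on
#' @param variable variable name
#' @param nBins number of bins (default 50)
#' @param breaks optional explicit bin edges (overrides nBins)
#' @param surface surface to normalize when \code{model} is a NicheModel
#' @param species species label when \code{model} is a bare vector
#' @return a [PNOProfile-class]
#' @export
computePNO <- function(model, stack, variable, nBins = 50, breaks = NULL,
                       surface = "logistic", species = "sp") {
  if (methods::is(model, "NicheModel")) {
    p <- surfaceDistribution(model, surface)
    species <- model@species
  } else {
    p <- model
    .checkDistribution(p, "suitability")
  }
  v <- envValues(stack, variable)[, 1]
  if (length(v) != length(p))
    stop("suitability length does not match the stack's non-masked cells")
  if (is.null(breaks)) {
    lo <- min(v); hi <- max(v)
    if (hi == lo) {
      warning("variable '", variable, "' is constant: degenerate single-bin profile")
      return(new("PNOProfile", species = species, variable = variable,
                 edges = c(lo - 0.5, lo + 0.5), mass = 1))
    }
    breaks <- seq(lo, hi, length.out = nBins + 1L)
  }
  bin <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  mass <- vapply(seq_len(length(breaks) - 1L),
                 function(k) sum(p[bin == k]), numeric(1))
  new("PNOProfile", species = species, variable = variable,
      edges = breaks, mass = mass / sum(mass))
}

#' Bin midpoints of a PNO profile
#' @param profile a [PNOProfile-class]
#' @export
pnoMidpoints <- function(profile) {
  (utils::head(profile@edges, -1L) + utils::tail(profile@edges, -1L)) / 2
}

#' Weighted mean of a PNO profile
#'
#' \eqn{\sum_{bins} midpoint \times mass}: the species' expected position
#' along the environmental axis, the univariate trait summarized by the
#' disparity and ordination analyses.
#'
#' @param profile a [PNOProfile-class]
#' @return value in variable units
#' @export
pnoWeightedMean <- function(profile) {
  sum(pnoMidpoints(profile) * profile@mass)
}

#' Ancestral tolerance reconstruction from PNO profiles
#'
#' Propagates intraspecific niche variation into the ancestral states: for
#' each of \code{nSamples} draws, one value (a bin midpoint, drawn with
#' probability equal to its bin mass) is sampled per tip and the
#' maximum-likelihood Brownian-motion ancestral states are computed; the
#' per-node collection of samples approximates the distribution of
#' ancestral tolerances.  With degenerate single-point profiles this
#' collapses to the plain BM reconstruction of those values.
#'
#' @param tree a \code{phylo} whose tip labels match the profile species
#' @param profiles named list of [PNOProfile-class] (one per tip, same
#'   variable)
#' @param nSamples number of random samples (default 100)
#' @param seed integer seed
#' @return an [AncestralTolerance-class]; node rows are named by ape node
#'   id, root first
#' @export
ancestralTolerance <- function(tree, profiles, nSamples = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  missing <- setdiff(tree$tip.label, names(profiles))
  if (length(missing) > 0)
    stop("no PNO profile for tip(s): ", paste(missing, collapse = ", "))
  vars <- unique(vapply(profiles[tree$tip.label], slot, character(1), "variable"))
  if (length(vars) != 1L)
    stop("profiles mix variables: ", paste(vars, collapse = ", "))
  tips <- tree$tip.label
  tipSamples <- vapply(tips, function(sp) {
    pr <- profiles[[sp]]
    mid <- pnoMidpoints(pr)
    mid[sample.int(length(mid), nSamples, replace = TRUE, prob = pr@mass)]
  }, numeric(nSamples))
  A <- .ancestralOperator(tree)        # GLS states are linear in tip values
  samples <- A %*% t(tipSamples)
  qs <- t(apply(samples, 1L, stats::quantile, probs = c(0.05, 0.95)))
  summary <- data.frame(node = as.integer(rownames(samples)),
                        mean = rowMeans(samples),
                        lower = qs[, 1], upper = qs[, 2])
  new("AncestralTolerance", variable = vars, samples = samples,
      tipSamples = t(tipSamples), summary = summary, nSamples = nSamples)
}
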