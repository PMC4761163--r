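#' @import methods
NULL

setOldClass("phylo")

#' Stack of co-registered environmental grids
#'
#' An \code{EnvStack} holds one or more environmental variables on a common
#' regular grid (ESRI ASCII convention: row 1 is the northernmost row, cells
#' are half-open \code{[x0, x0+cs)} in x and \code{(y0-cs, y0]} in y).  All
#' variables share one geotransform and one nodata mask; the mask is the
#' union of the per-variable nodata cells so that every analysis sees a
#' single common support.
#'
#' @slot grids named list of numeric matrices (one per variable), identical
#'   dimensions, row-major from the north.
#' @slot xll,yll x/y coordinate of the lower-left corner of the grid.
#' @slot cellsize cell size in map units (> 0).
#' @slot mask logical matrix, \code{TRUE} for valid (non-nodata) cells.
#' @seealso [readEnvStack()], [simulateEnvStack()], [envValues()]
#' @export
setClass("EnvStack",
  slots = c(grids = "list", xll = "numeric", yll = "numeric",
            cellsize = "numeric", mask = "matrix"))

setValidity("EnvStack", function(object) {
  g <- object@grids
  if (length(g) == 0L) return("EnvStack must contain at least one variable")
  if (is.null(names(g)) || anyDuplicated(names(g)) || any(!nzchar(names(g))))
    return("grids must be a uniquely named list")
  dims <- vapply(g, dim, integer(2))
  if (any(dims != dims[, 1])) return("all variables must share one grid geometry")
  if (!identical(dim(object@mask), dim(g[[1]])))
    return("mask dimensions must match the grids")
  if (length(object@cellsize) != 1L || object@cellsize <= 0)
    return("cellsize must be a single positive number")
  for (v in names(g)) {
    if (any(!is.finite(g[[v]][object@mask])))
      return(sprintf("variable '%s' has non-finite values on unmasked cells", v))
  }
  TRUE
})

#' Presence records for one species
#'
#' @slot species species name (must match a tree tip label downstream).
#' @slot points numeric matrix with columns \code{x}, \code{y} in map units.
#' @slot source free-text provenance.
#' @seealso [thinOccurrences()], [sampleOccurrences()], [readOccurrences()]
#' @export
setClass("OccurrenceSet",
  slots = c(species = "character", points = "matrix", source = "character"),
  prototype = prototype(source = NA_character_))

setValidity("OccurrenceSet", function(object) {
  if (length(object@species) != 1L || !nzchar(object@species))
    return("species must be a single non-empty name")
  p <- object@points
  if (ncol(p) != 2L) return("points must have two columns (x, y)")
  if (nrow(p) > 0 && any(!is.finite(p))) return("points must be finite")
  TRUE
})

#' Fitted maximum-entropy niche model
#'
#' The raw output is a Gibbs distribution over the non-masked grid cells
#' (summing to 1); the logistic output rescales it to \code{[0, 1]} using the
#' model entropy and the prevalence parameter tau.
#'
#' @slot species modeled species.
#' @slot variables environmental variables entering the feature set.
#' @slot lambda fitted feature weights (named).
#' @slot beta regularization multiplier; \code{betaJ} the per-feature
#'   penalties \code{beta * sd_presence(f_j) / sqrt(m)}.
#' @slot featureCenter,featureScale background mean/SD used to standardize
#'   features, so models fitted to different occurrence sets share one
#'   feature space.
#' @slot raw matrix of the Gibbs probabilities (NA on masked cells).
#' @slot logistic matrix of logistic suitability in \code{[0, 1]}.
#' @slot entropy entropy H of the raw distribution.
#' @slot tau logistic prevalence (default 0.5).
#' @slot mtp minimum training presence threshold (logistic units).
#' @slot converged,nIter,objective optimizer diagnostics (objective is the
#'   per-sweep trace of the penalized negative log-likelihood).
#' @seealso [fitMaxent()], [applyMTP()], [surfaceDistribution()]
#' @export
setClass("NicheModel",
  slots = c(species = "character", variables = "character", lambda = "numeric",
            beta = "numeric", betaJ = "numeric",
            featureCenter = "numeric", featureScale = "numeric",
            raw = "matrix", logistic = "matrix",
            entropy = "numeric", tau = "numeric", mtp = "numeric",
            converged = "logical", nIter = "numeric", objective = "numeric"))

setValidity("NicheModel", function(object) {
  ok <- object@raw[!is.na(object@raw)]
  if (abs(sum(ok) - 1) > 1e-9) return("raw distribution must sum to 1")
  lg <- object@logistic[!is.na(object@logistic)]
  if (any(lg < -1e-12 | lg > 1 + 1e-12)) return("logistic values must lie in [0, 1]")
  if (object@entropy < 0) return("entropy must be non-negative")
  TRUE
})

#' Predicted niche occupancy profile
#'
#' Per species and environmental variable: the probability that suitability
#' mass falls in each bin of the variable's observed range.  Bin edges are
#' shared across species for a given variable so profiles are comparable.
#'
#' @slot species,variable identifiers.
#' @slot edges strictly increasing bin edges (length nBins + 1).
#' @slot mass per-bin probability, summing to 1.
#' @seealso [computePNO()], [pnoWeightedMean()], [ancestralTolerance()]
#' @export
setClass("PNOProfile",
  slots = c(species = "character", variable = "character",
            edges = "numeric", mass = "numeric"))

setValidity("PNOProfile", function(object) {
  if (length(object@mass) != length(object@edges) - 1L)
    return("mass must have one entry per bin")
  if (any(diff(object@edges) <= 0)) return("bin edges must be strictly increasing")
  if (any(object@mass < -1e-12)) return("bin mass must be non-negative")
  if (abs(sum(object@mass) - 1) > 1e-9) return("bin mass must sum to 1")
  TRUE
})

#' Pairwise niche overlap matrices
#'
#' Schoener's D and Warren's I for every species pair, computed on
#' normalized suitability surfaces.  Both metrics lie in \code{[0, 1]} and
#' I >= D entrywise.
#'
#' @slot species species order of the matrices.
#' @slot D,I symmetric overlap matrices with unit diagonal.
#' @slot surface which model surface was normalized ("logistic" or "raw").
#' @seealso [nicheOverlap()], [schoenerD()], [warrenI()]
#' @export
setClass("OverlapMatrix",
  slots = c(species = "character", D = "matrix", I = "matrix",
            surface = "character"))

setValidity("OverlapMatrix", function(object) {
  n <- length(object@species)
  for (nm in c("D", "I")) {
    M <- slot(object, nm)
    if (!all(dim(M) == n)) return(sprintf("%s must be %d x %d", nm, n, n))
    if (max(abs(M - t(M))) > 1e-9) return(sprintf("%s must be symmetric", nm))
    if (max(abs(diag(M) - 1)) > 1e-9) return(sprintf("%s must have unit diagonal", nm))
    if (min(M) < -1e-9 || max(M) > 1 + 1e-9) return(sprintf("%s must lie in [0, 1]", nm))
  }
  if (min(object@I - object@D) < -1e-9) return("I must dominate D entrywise")
  TRUE
})

#' Result of a niche randomization test
#'
#' Holds the observed overlap (both D and I), the null sample of the
#' randomization, the one-sided empirical percentile bounds at the
#' configured confidence, and the verdict for the metric the test was run
#' on.  Verdicts: \code{"identity-not-rejected"} / \code{"identity-rejected"}
#' for the identity test; \code{"conservatism"} / \code{"divergence"} /
#' \code{"n.s."} for the background-similarity test.
#'
#' @seealso [identityTest()], [backgroundTest()]
#' @export
setClass("RandomizationResult",
  slots = c(test = "character", speciesA = "character", speciesB = "character",
            direction = "character", metric = "character",
            observed = "numeric", null = "matrix",
            lower = "numeric", upper = "numeric",
            verdict = "character", pValue = "numeric",
            conf = "numeric", nReplicates = "numeric"))

setValidity("RandomizationResult", function(object) {
  if (nrow(object@null) != object@nReplicates)
    return("null sample length must equal the configured number of replicates")
  TRUE
})

#' Age-range correlation result
#'
#' @slot nodes data frame with one row per internal node: \code{node},
#'   \code{age}, \code{overlap}, OLS \code{fit}, interval \code{lwr}/\code{upr}
#'   and the outlier flag (\code{"above"}, \code{"below"} or \code{""}).
#' @slot slope,intercept OLS coefficients of overlap on node age.
#' @slot pValue two-sided permutation p-value for the slope (NA when run
#'   with zero permutations).
#' @seealso [ageRangeCorrelation()]
#' @export
setClass("ARCResult",
  slots = c(nodes = "data.frame", slope = "numeric", intercept = "numeric",
            pValue = "numeric", weighting = "character", metric = "character",
            conf = "numeric", interval = "character"))

#' Ancestral tolerance reconstruction
#'
#' Monte-Carlo sample of maximum-likelihood Brownian-motion ancestral states
#' obtained by repeatedly drawing tip values from each species' PNO profile.
#'
#' @slot variable environmental variable.
#' @slot samples matrix (internal nodes x nSamples) of reconstructed values.
#' @slot tipSamples matrix (tips x nSamples) of the drawn tip values.
#' @slot summary per-node mean and 5--95 % band.
#' @seealso [ancestralTolerance()]
#' @export
setClass("AncestralTolerance",
  slots = c(variable = "character", samples = "matrix", tipSamples = "matrix",
            summary = "data.frame", nSamples = "numeric"))

setValidity("AncestralTolerance", function(object) {
  if (ncol(object@samples) != object@nSamples)
    return("sample size must equal the configured nSamples")
  TRUE
})

#' Disparity-through-time curve with MDI
#'
#' @slot times relative times (0 at the root, 1 at the present) of the curve
#'   evaluation points (internal-node heights plus the present).
#' @slot observed observed mean relative subclade disparity.
#' @slot simMean,lower,upper pointwise mean and confidence envelope of the
#'   Brownian-motion simulations.
#' @slot mdi area (trapezoid) between the observed curve and the simulated
#'   mean; negative when observed disparity falls below the Brownian
#'   expectation.
#' @slot nodes per-node table with observed disparity, rank among
#'   simulations, and one-tailed (high) / two-tailed p-values.
#' @seealso [dttCurve()], [mdi()]
#' @export
setClass("DTTCurve",
  slots = c(times = "numeric", observed = "numeric",
            simMean = "numeric", lower = "numeric", upper = "numeric",
            mdi = "numeric", nodes = "data.frame",
            nSims = "numeric", conf = "numeric"))

#' Phylogenetic principal components analysis result
#'
#' @slot mean GLS phylogenetic mean vector a.
#' @slot evolCov evolutionary covariance matrix R (GLS, on the analyzed
#'   scale).
#' @slot values,vectors eigenvalues (non-increasing) and eigenvectors.
#' @slot scores per-species component scores.
#' @slot varExplained fraction of variance per component (sums to 1).
#' @slot mode "cov" or "corr" (unit-variance scaling).
#' @seealso [phyloPCA()]
#' @export
setClass("PPCAResult",
  slots = c(mean = "numeric", evolCov = "matrix", values = "numeric",
            vectors = "matrix", scores = "matrix", varExplained = "numeric",
            mode = "character"))

setValidity("PPCAResult", function(object) {
  if (is.unsorted(rev(object@values + 1e-12))) return("eigenvalues must be non-increasing")
  if (min(object@values) < -1e-8 * max(abs(object@values)))
    return("eigenvalues must be non-negative")
  TRUE
})

#' Phylogenetic MANOVA result
#'
#' Wilks' Lambda with its exact-F transform, plus a null F sample generated
#' by multivariate Brownian-motion simulation on the tree with the group
#' labels held fixed.
#'
#' @seealso [phyloMANOVA()]
#' @export
setClass("PhyloMANOVAResult",
  slots = c(wilks = "numeric", F = "numeric", df1 = "numeric", df2 = "numeric",
            pValue = "numeric", nullF = "numeric", nSims = "numeric",
            groups = "factor"))
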