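# Accessor generics and show methods for the core containers.

#' Variable names of an EnvStack
#' @param x an [EnvStack-class]
#' @return character vector of variable names
#' @export
envVariables <- function(x) names(x@grids)

#' Grid matrix of one variable
#' @param x an [EnvStack-class]
#' @param variable variable name
#' @return numeric matrix (row 1 = northernmost row)
#' @export
envGrid <- function(x, variable) {
  if (!variable %in% envVariables(x))
    stop("unknown variable: ", variable)
  x@grids[[variable]]
}

#' Validity mask of an EnvStack
#' @param x an [EnvStack-class]
#' @return logical matrix, TRUE on valid cells
#' @export
envMask <- function(x) x@mask

#' Cell size of an EnvStack
#' @param x an [EnvStack-class]
#' @export
envCellSize <- function(x) x@cellsize

#' Extent of an EnvStack
#' @param x an [EnvStack-class]
#' @return named numeric (xmin, xmax, ymin, ymax)
#' @export
envExtent <- function(x) {
  nr <- nrow(x@mask); nc <- ncol(x@mask); cs <- x@cellsize
  c(xmin = x@xll, xmax = x@xll + nc * cs,
    ymin = x@yll, ymax = x@yll + nr * cs)
}

#' Values of the non-masked cells
#'
#' Returns the environmental values on the common support as a cells x
#' variables matrix.  Cell order is the column-major order of
#' \code{which(envMask(x))} and is shared by [envCellCenters()] and the
#' model surfaces, so rows line up across all per-cell quantities.
#'
#' @param x an [EnvStack-class]
#' @param variables subset of variables (default all)
#' @return numeric matrix, one row per non-masked cell
#' @export
envValues <- function(x, variables = envVariables(x)) {
  idx <- which(x@mask)
  out <- vapply(variables, function(v) envGrid(x, v)[idx], numeric(length(idx)))
  if (length(idx) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, variables))
  out
}

#' Centers of the non-masked cells
#' @param x an [EnvStack-class]
#' @return matrix with columns x, y in [envValues()] cell order
#' @export
envCellCenters <- function(x) {
  nr <- nrow(x@mask); cs <- x@cellsize
  idx <- which(x@mask)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  ytop <- x@yll + nr * cs
  cbind(x = x@xll + (col - 0.5) * cs, y = ytop - (row - 0.5) * cs)
}

#' Subset an EnvStack by variable
#' @param x an [EnvStack-class]
#' @param i character or integer index of variables to keep
#' @param j,...,drop ignored
#' @export
setMethod("[", "EnvStack", function(x, i, j, ..., drop = FALSE) {
  g <- x@grids[i]
  if (any(vapply(g, is.null, logical(1)))) stop("unknown variable in subset")
  new("EnvStack", grids = g, xll = x@xll, yll = x@yll,
      cellsize = x@cellsize, mask = x@mask)
})

setMethod("show", "EnvStack", function(object) {
  d <- dim(object@mask)
  cat(sprintf("EnvStack: %d variable(s) on a %d x %d grid (cell size %g)\n",
              length(object@grids), d[1], d[2], object@cellsize))
  cat(sprintf("  variables: %s\n", paste(envVariables(object), collapse = ", ")))
  cat(sprintf("  valid cells: %d / %d\n", sum(object@mask), length(object@mask)))
})

#' Species name of an object
#' @param x an [OccurrenceSet-class], [NicheModel-class] or [PNOProfile-class]
#' @export
speciesName <- function(x) x@species

#' Occurrence coordinates
#' @param x an [OccurrenceSet-class]
#' @return numeric matrix with columns x, y
#' @export
occPoints <- function(x) x@points

#' Number of occurrence records
#' @param x an [OccurrenceSet-class]
#' @export
nOcc <- function(x) nrow(x@points)

setMethod("show", "OccurrenceSet", function(object) {
  cat(sprintf("OccurrenceSet: '%s', %d point(s)\n", object@species, nOcc(object)))
})

setMethod("show", "NicheModel", function(object) {
  cat(sprintf("NicheModel: '%s' (%d features over %s)\n", object@species,
              length(object@lambda), paste(object@variables, collapse = ", ")))
  cat(sprintf("  entropy %.4f | MTP %.4f | %s after %d sweep(s)\n",
              object@entropy, object@mtp,
              if (object@converged) "converged" else "NOT converged", object@nIter))
})

setMethod("show", "PNOProfile", function(object) {
  cat(sprintf("PNOProfile: '%s' on %s, %d bins, weighted mean %.4g\n",
              object@species, object@variable, length(object@mass),
              pnoWeightedMean(object)))
})

setMethod("show", "OverlapMatrix", function(object) {
  n <- length(object@species)
  off <- upper.tri(object@D)
  cat(sprintf("OverlapMatrix: %d species (%s surfaces)\n", n, object@surface))
  if (n > 1)
    cat(sprintf("  mean D %.3f | mean I %.3f\n",
                mean(object@D[off]), mean(object@I[off])))
})

setMethod("show", "RandomizationResult", function(object) {
  cat(sprintf("%s test: %s vs %s (%s), metric %s\n", object@test,
              object@speciesA, object@speciesB, object@direction, object@metric))
  cat(sprintf("  observed %s = %.4f | null bounds [%.4f, %.4f] (%d reps, conf %.2f)\n",
              object@metric, object@observed[object@metric],
              object@lower[object@metric], object@upper[object@metric],
              object@nReplicates, object@conf))
  cat(sprintf("  verdict: %s (p = %.3f)\n", object@verdict, object@pValue))
})

setMethod("show", "ARCResult", function(object) {
  cat(sprintf("Age-range correlation (%s weighting, %s metric): slope %.4g, intercept %.4g\n",
              object@weighting, object@metric, object@slope, object@intercept))
  cat(sprintf("  permutation p = %s | %d node(s), %d outlier(s)\n",
              format(object@pValue, digits = 3), nrow(object@nodes),
              sum(nzchar(object@nodes$flag))))
})

setMethod("show", "AncestralTolerance", function(object) {
  cat(sprintf("AncestralTolerance: %s, %d internal node(s) x %d sample(s)\n",
              object@variable, nrow(object@samples), object@nSamples))
})

setMethod("show", "DTTCurve", function(object) {
  cat(sprintf("DTTCurve: %d evaluation point(s), MDI = %.4f (%d sims, conf %.2f)\n",
              length(object@times), object@mdi, object@nSims, object@conf))
})

setMethod("show", "PPCAResult", function(object) {
  cat(sprintf("Phylogenetic PCA (%s mode): %d component(s)\n",
              object@mode, length(object@values)))
  ve <- utils::head(object@varExplained, 4)
  cat(sprintf("  var explained: %s\n",
              paste(sprintf("%.1f%%", 100 * ve), collapse = ", ")))
})

setMethod("show", "PhyloMANOVAResult", function(object) {
  cat(sprintf("Phylogenetic MANOVA: Wilks %.4f, F(%g, %g) = %.3f, simulation p = %.4g (%d sims)\n",
              object@wilks, object@df1, object@df2, object@F, object@pValue,
              object@nSims))
})
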