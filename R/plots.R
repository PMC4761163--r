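# Base-graphics plot methods for the main result containers.

#' @describeIn ageRangeCorrelation Plot node overlap against node age with
#'   the fitted line and per-node interval; flagged nodes are highlighted.
#' @param x an [ARCResult-class]
#' @param y ignored
#' @param ... passed to \code{plot}
#' @export
setMethod("plot", signature(x = "ARCResult", y = "missing"),
  function(x, y, ...) {
    d <- x@nodes[order(x@nodes$age), ]
    graphics::plot(d$age, d$overlap, xlab = "node age", ylab = "niche overlap",
                   pch = 19, col = ifelse(nzchar(d$flag), "firebrick", "black"),
                   ylim = range(c(d$overlap, d$lwr, d$upr)), ...)
    graphics::abline(x@intercept, x@slope)
    graphics::lines(d$age, d$lwr, lty = 3)
    graphics::lines(d$age, d$upr, lty = 3)
    invisible(x)
  })

#' @describeIn mdi Plot the observed disparity-through-time curve over the
#'   Brownian-motion envelope.
#' @param x a [DTTCurve-class]
#' @param y ignored
#' @param ... passed to \code{plot}
#' @export
setMethod("plot", signature(x = "DTTCurve", y = "missing"),
  function(x, y, ...) {
    graphics::plot(x@times, x@observed, type = "s", lwd = 2,
                   xlab = "relative time", ylab = "mean relative disparity",
                   ylim = range(c(x@observed, x@lower, x@upper)), ...)
    graphics::lines(x@times, x@simMean, type = "s", lty = 2)
    graphics::lines(x@times, x@lower, type = "s", lty = 3, col = "grey50")
    graphics::lines(x@times, x@upper, type = "s", lty = 3, col = "grey50")
    graphics::legend("topleft", bty = "n", lty = c(1, 2),
                     legend = c("observed", "Brownian expectation"))
    invisible(x)
  })

#' Ancestral tolerance plot
#'
#' Draws the per-node reconstructed tolerance bands of one variable through
#' time together with the tip values, the lines connecting each node to its
#' ancestor tracing the inferred history along the phylogeny (branch
#' crossings indicate divergent evolution in niche space).
#'
#' @param tree the \code{phylo} the reconstruction was computed on
#' @param at an [AncestralTolerance-class]
#' @param tipValues optional named tip values to draw at the present
#'   (default: the mean of each tip's sampled values)
#' @param ... passed to \code{plot}
#' @return invisibly, \code{at}
#' @export
plotAncestralTolerance <- function(tree, at, tipValues = NULL, ...) {
  depth <- max(ape::node.depth.edgelength(tree))
  n <- ape::Ntip(tree)
  nodeTime <- c(rep(depth, n), depth - ape::branching.times(tree))
  if (is.null(tipValues))
    tipValues <- stats::setNames(rowMeans(at@tipSamples), tree$tip.label)
  vals <- c(tipValues[tree$tip.label], rowMeans(at@samples))
  graphics::plot(NA, xlim = c(0, depth * 1.15), ylim = range(vals),
                 xlab = "time", ylab = at@variable, ...)
  for (k in seq_len(nrow(tree$edge))) {
    u <- tree$edge[k, 1]; v <- tree$edge[k, 2]
    graphics::segments(nodeTime[u], vals[u], nodeTime[v], vals[v])
  }
  s <- at@summary
  graphics::arrows(nodeTime[s$node], s$lower, nodeTime[s$node], s$upper,
                   length = 0.02, angle = 90, code = 3, col = "grey60")
  graphics::text(depth, vals[seq_len(n)], tree$tip.label, pos = 4, cex = 0.7)
  invisible(at)
}
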