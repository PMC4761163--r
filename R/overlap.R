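# Niche-overlap statistics on normalized suitability surfaces.

.checkDistribution <- function(p, what) {
  if (abs(sum(p) - 1) > 1e-6)
    stop(what, " must be normalized to sum 1 (got ", format(sum(p)), ")")
  if (any(p < 0)) stop(what, " must be non-negative")
  invisible(TRUE)
}

#' Schoener's D niche overlap
#'
#' \eqn{D = 1 - \frac12 \sum_i |p_i - q_i|} between two cell distributions;
#' 0 for disjoint support, 1 for identical distributions.
#'
#' @param pX,pY numeric distributions over the same cells, each summing to 1
#' @return overlap in \code{[0, 1]}
#' @examples
#' schoenerD(c(0.6, 0.4), c(0.4, 0.6))  # 0.8
#' @export
schoenerD <- function(pX, pY) {
  .checkDistribution(pX, "pX"); .checkDistribution(pY, "pY")
  1 - 0.5 * sum(abs(pX - pY))
}

#' Warren's I niche overlap
#'
#' One minus half the squared Hellinger distance,
#' \eqn{I = 1 - \frac12 \sum_i (\sqrt{p_i} - \sqrt{q_i})^2}.  Dominates
#' Schoener's D for every pair of distributions.
#'
#' @param pX,pY numeric distributions over the same cells, each summing to 1
#' @return overlap in \code{[0, 1]}
#' @examples
#' warrenI(c(1, 0), c(0.5, 0.5))  # sqrt(2)/2
#' @export
warrenI <- function(pX, pY) {
  .checkDistribution(pX, "pX"); .checkDistribution(pY, "pY")
  1 - 0.5 * sum((sqrt(pX) - sqrt(pY))^2)
}

#' Normalized suitability distribution of a model
#'
#' The model surface (logistic by default, following the convention of
#' standardizing surfaces before overlap; raw optionally) renormalized to
#' sum 1 over the non-masked cells, in [envValues()] cell order.
#'
#' @param model a [NicheModel-class]
#' @param surface "logistic" or "raw"
#' @return numeric distribution over the non-masked cells
#' @export
surfaceDistribution <- function(model, surface = c("logistic", "raw")) {
  surface <- match.arg(surface)
  s <- slot(model, surface)
  v <- s[!is.na(s)]
  v / sum(v)
}

#' Pairwise niche overlap matrices
#'
#' Schoener's D and Warren's I for every pair of models, computed on their
#' normalized surfaces over the shared support.
#'
#' @param models named list of [NicheModel-class] on one stack
#' @param surface "logistic" (default) or "raw"
#' @return an [OverlapMatrix-class]
#' @export
nicheOverlap <- function(models, surface = c("logistic", "raw")) {
  surface <- match.arg(surface)
  sp <- vapply(models, speciesName, character(1))
  names(models) <- sp
  P <- vapply(models, surfaceDistribution, surface = surface,
              numeric(sum(!is.na(models[[1]]@raw))))
  n <- length(sp)
  D <- I <- diag(1, n)
  dimnames(D) <- dimnames(I) <- list(sp, sp)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- schoenerD(P[, i], P[, j])
      I[i, j] <- I[j, i] <- warrenI(P[, i], P[, j])
    }
  }
  new("OverlapMatrix", species = sp, D = D, I = I, surface = surface)
}
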