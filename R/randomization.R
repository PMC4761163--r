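# Randomization tests for niche identity and background similarity, and
# the within-clade summary of verdicts.

.overlapOfModels <- function(mA, mB, surface) {
  pA <- surfaceDistribution(mA, surface)
  pB <- surfaceDistribution(mB, surface)
  c(D = schoenerD(pA, pB), I = warrenI(pA, pB))
}

#' Niche identity test
#'
#' Tests whether two species' niches are identical.  The observed statistic
#' is the overlap of the two fitted models; the null distribution is built
#' by pooling all occurrence points, randomly repartitioning them into
#' pseudo-samples of the original sizes, and refitting both models.
#' Identity is rejected when the observed overlap falls below the one-sided
#' lower percentile bound at the configured confidence (empirical order
#' statistic, rank \code{ceiling(q (n+1))}).  A replicate whose model fit
#' fails is re-drawn, capped at three times the replicate budget.
#'
#' @param stack an [EnvStack-class]
#' @param occA,occB [OccurrenceSet-class] of the two species (each passing
#'   the ENM minimum-occurrence rule)
#' @param metric "D" or "I": the metric the verdict is based on
#' @param nReplicates null sample size (default 100)
#' @param conf confidence level (default 0.95, one-sided low)
#' @param seed integer seed
#' @param surface overlap surface (see [surfaceDistribution()])
#' @param ... further arguments to [fitMaxent()] (same settings are used
#'   for observed and null fits)
#' @return a [RandomizationResult-class]
#' @export
identityTest <- function(stack, occA, occB, metric = c("D", "I"),
                         nReplicates = 100, conf = 0.95, seed = NULL,
                         surface = "logistic", ...) {
  metric <- match.arg(metric)
  if (!is.null(seed)) set.seed(seed)
  mA <- fitMaxent(stack, occA, ...)
  mB <- fitMaxent(stack, occB, ...)
  obs <- .overlapOfModels(mA, mB, surface)
  pool <- rbind(occA@points, occB@points)
  nA <- nOcc(occA)
  null <- matrix(NA_real_, nReplicates, 2, dimnames = list(NULL, c("D", "I")))
  done <- 0L; attempts <- 0L
  while (done < nReplicates && attempts < 3L * nReplicates) {
    attempts <- attempts + 1L
    perm <- sample.int(nrow(pool))
    pA <- methods::initialize(occA, points = pool[perm[seq_len(nA)], , drop = FALSE])
    pB <- methods::initialize(occB, points = pool[perm[-seq_len(nA)], , drop = FALSE])
    rep <- tryCatch({
      rA <- fitMaxent(stack, pA, ...)
      rB <- fitMaxent(stack, pB, ...)
      .overlapOfModels(rA, rB, surface)
    }, error = function(e) {
      message("identity test replicate re-drawn: ", conditionMessage(e))
      NULL
    })
    if (!is.null(rep)) {
      done <- done + 1L
      null[done, ] <- rep
    }
  }
  if (done < nReplicates)
    stop("identity test: could not complete ", nReplicates,
         " replicates within the attempt budget")
  lower <- c(D = percentileBound(null[, "D"], 1 - conf),
             I = percentileBound(null[, "I"], 1 - conf))
  upper <- c(D = percentileBound(null[, "D"], conf),
             I = percentileBound(null[, "I"], conf))
  pValue <- (1 + sum(null[, metric] <= obs[metric])) / (nReplicates + 1)
  verdict <- if (obs[metric] < lower[metric]) "identity-rejected"
             else "identity-not-rejected"
  new("RandomizationResult", test = "identity",
      speciesA = occA@species, speciesB = occB@species, direction = "pooled",
      metric = metric, observed = obs, null = null,
      lower = lower, upper = upper, verdict = verdict, pValue = pValue,
      conf = conf, nReplicates = nReplicates)
}

# Ray-casting point-in-polygon; polygon as two-column matrix of vertices.
.inPolygon <- function(pts, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

.distToSegments <- function(pts, poly) {
  n <- nrow(poly)
  d2 <- rep(Inf, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    a <- poly[j, ]; b <- poly[i, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, nrow(pts)) else
      pmin(1, pmax(0, ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2))
    dx <- pts[, 1] - (a[1] + t * ab[1])
    dy <- pts[, 2] - (a[2] + t * ab[2])
    d2 <- pmin(d2, dx^2 + dy^2)
    j <- i
  }
  sqrt(d2)
}

#' Background mask from a species' observed distribution
#'
#' The "available environment" of a species: all non-masked cells whose
#' center lies inside the convex hull of the occurrence points buffered by
#' \code{buffer} cells.  The background-similarity tests draw their
#' pseudolocalities from this region; the extent definition is a
#' configurable convention, not an assertion about any particular study.
#'
#' @param stack an [EnvStack-class]
#' @param occ an [OccurrenceSet-class]
#' @param buffer buffer width in cells (default 5)
#' @return logical matrix, TRUE on background cells
#' @export
backgroundMask <- function(stack, occ, buffer = 5) {
  pts <- occ@points
  centers <- envCellCenters(stack)
  radius <- buffer * stack@cellsize
  if (nrow(pts) == 1L) {
    ok <- sqrt((centers[, 1] - pts[1, 1])^2 +
               (centers[, 2] - pts[1, 2])^2) <= radius
  } else if (nrow(pts) == 2L || length(unique(grDevices::chull(pts))) < 3L) {
    ok <- .distToSegments(centers, pts[!duplicated(pts), , drop = FALSE]) <= radius
  } else {
    hull <- pts[grDevices::chull(pts), , drop = FALSE]
    ok <- .inPolygon(centers, hull) | .distToSegments(centers, hull) <= radius
  }
  out <- matrix(FALSE, nrow(stack@mask), ncol(stack@mask))
  out[which(stack@mask)[ok]] <- TRUE
  out
}

#' Background similarity test
#'
#' Tests whether the observed niche overlap between species A and B
#' exceeds (niche conservatism) or falls short of (niche divergence) the
#' overlap expected from B's available environment.  Each null replicate
#' draws \code{nOcc(occB)} distinct pseudolocality cells uniformly from B's
#' background, fits a model to them, and computes its overlap with A's real
#' model.  The verdict is "conservatism" when the observed overlap is above
#' the one-sided upper bound, "divergence" when below the lower bound, and
#' "n.s." otherwise.  Run the test once per direction of the pair.
#'
#' @param stack an [EnvStack-class]
#' @param occA occurrence set of the focal species (model kept fixed)
#' @param occB occurrence set whose background supplies the pseudolocalities
#' @param backgroundB logical matrix of background cells (default:
#'   [backgroundMask()] of occB)
#' @param direction label stored in the result (default "A->B")
#' @param nReplicates,conf,seed,surface as in [identityTest()]
#' @param metric "D" or "I"
#' @param buffer buffer for the default background mask
#' @param ... further arguments to [fitMaxent()]
#' @return a [RandomizationResult-class]
#' @export
backgroundTest <- function(stack, occA, occB, backgroundB = NULL,
                           direction = "A->B", metric = c("D", "I"),
                           nReplicates = 100, conf = 0.95, seed = NULL,
                           surface = "logistic", buffer = 5, ...) {
  metric <- match.arg(metric)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(backgroundB)) backgroundB <- backgroundMask(stack, occB, buffer)
  bgCells <- which(backgroundB & stack@mask)
  nB <- nOcc(occB)
  if (length(bgCells) < nB)
    stop("background holds ", length(bgCells), " cells but ", nB,
         " pseudolocalities are needed")
  mA <- fitMaxent(stack, occA, ...)
  mB <- fitMaxent(stack, occB, ...)
  obs <- .overlapOfModels(mA, mB, surface)
  nr <- nrow(stack@mask); cs <- stack@cellsize
  ytop <- stack@yll + nr * cs
  null <- matrix(NA_real_, nReplicates, 2, dimnames = list(NULL, c("D", "I")))
  done <- 0L; attempts <- 0L
  while (done < nReplicates && attempts < 3L * nReplicates) {
    attempts <- attempts + 1L
    cells <- sample(bgCells, nB)
    row <- (cells - 1L) %% nr + 1L
    col <- (cells - 1L) %/% nr + 1L
    pts <- cbind(x = stack@xll + (col - 0.5) * cs, y = ytop - (row - 0.5) * cs)
    pseudo <- methods::initialize(occB, points = pts)
    rep <- tryCatch(
      .overlapOfModels(mA, fitMaxent(stack, pseudo, ...), surface),
      error = function(e) {
        message("background test replicate re-drawn: ", conditionMessage(e))
        NULL
      })
    if (!is.null(rep)) {
      done <- done + 1L
      null[done, ] <- rep
    }
  }
  if (done < nReplicates)
    stop("background test: could not complete ", nReplicates,
         " replicates within the attempt budget")
  lower <- c(D = percentileBound(null[, "D"], 1 - conf),
             I = percentileBound(null[, "I"], 1 - conf))
  upper <- c(D = percentileBound(null[, "D"], conf),
             I = percentileBound(null[, "I"], conf))
  verdict <- if (obs[metric] > upper[metric]) "conservatism"
             else if (obs[metric] < lower[metric]) "divergence"
             else "n.s."
  pValue <- min(
    (1 + sum(null[, metric] >= obs[metric])) / (nReplicates + 1),
    (1 + sum(null[, metric] <= obs[metric])) / (nReplicates + 1))
  new("RandomizationResult", test = "background",
      speciesA = occA@species, speciesB = occB@species, direction = direction,
      metric = metric, observed = obs, null = null,
      lower = lower, upper = upper, verdict = verdict, pValue = pValue,
      conf = conf, nReplicates = nReplicates)
}

#' Enumerate within-clade species pairs
#'
#' @param clades named character vector mapping species to clade
#' @return data frame with columns \code{clade}, \code{speciesA},
#'   \code{speciesB}, one row per unordered within-clade pair
#' @export
enumerateCladePairs <- function(clades) {
  out <- data.frame(clade = character(0), speciesA = character(0),
                    speciesB = character(0), stringsAsFactors = FALSE)
  for (cl in unique(clades)) {
    sp <- names(clades)[clades == cl]
    if (length(sp) < 2L) next
    pr <- utils::combn(sp, 2L)
    out <- rbind(out, data.frame(clade = cl, speciesA = pr[1, ],
                                 speciesB = pr[2, ], stringsAsFactors = FALSE))
  }
  out
}

#' Summarize pairwise test verdicts within clades
#'
#' Counts, per clade and verdict, how many of the clade's unordered species
#' pairs received that verdict, and reports the percentage rounded to an
#' integer (\code{round(100 k / n)}).  A pair tested in both directions
#' counts once per verdict if either direction produced it.
#'
#' @param results data frame with columns \code{speciesA}, \code{speciesB},
#'   \code{verdict} (possibly several rows per pair), or a list of
#'   [RandomizationResult-class]
#' @param clades named character vector mapping every tested species to
#'   exactly one clade
#' @return data frame with columns \code{clade}, \code{nPairs},
#'   \code{verdict}, \code{count}, \code{percent}
#' @export
summarizeWithinClade <- function(results, clades) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, lapply(results, function(r)
      data.frame(speciesA = r@speciesA, speciesB = r@speciesB,
                 verdict = r@verdict, stringsAsFactors = FALSE)))
  sp <- unique(c(results$speciesA, results$speciesB))
  missing <- setdiff(sp, names(clades))
  if (length(missing) > 0)
    stop("species without clade label: ", paste(missing, collapse = ", "))
  pairs <- enumerateCladePairs(clades)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  rkey <- key(results$speciesA, results$speciesB)
  verdicts <- sort(unique(results$verdict))
  out <- NULL
  for (cl in unique(pairs$clade)) {
    pc <- pairs[pairs$clade == cl, ]
    n <- nrow(pc)
    pkey <- key(pc$speciesA, pc$speciesB)
    for (v in verdicts) {
      hit <- unique(rkey[results$verdict == v])
      k <- sum(pkey %in% hit)
      out <- rbind(out, data.frame(clade = cl, nPairs = n, verdict = v,
                                   count = k, percent = round(100 * k / n),
                                   stringsAsFactors = FALSE))
    }
  }
  out
}
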