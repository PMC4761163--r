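# End-to-end orchestration: thin -> decorrelate -> ENM -> overlap ->
# identity/background tests -> PNO -> ancestral tolerances -> ARC -> DTT ->
# pPCA/MANOVA, from one configuration with derived per-stage seeds.

#' Pipeline configuration
#'
#' Returns the default run configuration.  The defaults are the analysis
#' settings of a standard phyloclimatic study: 10 AUC replicates with a
#' 59/41 train/test split and a 0.7 mean-AUC gate, 100 randomization
#' replicates at confidence 0.95, 50 PNO bins, 1000 DTT and MANOVA
#' simulations, a 5-occurrence modeling minimum, and regularization
#' multiplier 1.  Override any entry via \code{...}.
#'
#' @param ... named overrides of the defaults
#' @return named list
#' @export
runConfig <- function(...) {
  cfg <- list(
    thinDist = 0,            # map units; set > 0 to thin occurrences
    rThreshold = 0.9,        # variable decorrelation cutoff
    priority = NULL,         # variable priority order (default: stack order)
    beta = 1,                # ENM regularization multiplier
    maxIter = 1000,
    minOccurrences = 5,
    aucReplicates = 10,
    trainFrac = 0.59,
    aucGate = 0.7,
    surface = "logistic",
    metric = "D",
    testReplicates = 100,
    conf = 0.95,
    testDirections = "both", # background test: "both" or "forward"
    buffer = 5,              # background mask buffer (cells)
    pnoBins = 50,
    atSamples = 100,         # ancestral tolerance samples
    arcWeighting = "ft",
    arcPermutations = 1000,
    dttSims = 1000,
    manovaSims = 1000,
    nComponents = 4,         # principal components entering the MANOVA
    seed = 1
  )
  override <- list(...)
  bad <- setdiff(names(override), names(cfg))
  if (length(bad) > 0) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(override)] <- override
  cfg
}

.stageLog <- function(log, stage, t0, ...) {
  entry <- c(list(stage = stage, seconds = round(as.numeric(Sys.time()) - t0, 2)),
             list(...))
  message(sprintf("[%s] %s (%.1fs)", format(Sys.time(), "%H:%M:%S"),
                  stage, entry$seconds))
  c(log, list(entry))
}

#' Run the full phyloclimatic analysis
#'
#' Orchestrates every stage on one dataset: occurrence validation and
#' thinning, environmental-variable decorrelation, per-species niche models
#' with AUC evaluation (species under the occurrence minimum are excluded
#' with a logged notice), pairwise overlap, within-clade identity and
#' background tests, PNO profiles and weighted means, ancestral tolerance
#' reconstruction, age-range correlation, disparity-through-time with MDI
#' per variable, and (when \code{groups} is given) phylogenetic PCA and
#' MANOVA.  All stochastic stages derive their seeds from
#' \code{config$seed} via [deriveSeed()], so a rerun with the same inputs
#' and configuration reproduces every number exactly.
#'
#' @param stack an [EnvStack-class]
#' @param occurrences named list of [OccurrenceSet-class]
#' @param tree ultrametric \code{phylo}; tip labels = species names
#' @param clades named character species -> clade
#' @param groups optional named character species -> group (two or more
#'   levels) for the MANOVA
#' @param config list from [runConfig()]
#' @param outDir optional directory; when given, stage outputs (TSV/JSON,
#'   and a manifest of settings and seeds) are written there
#' @return list with elements \code{models}, \code{auc}, \code{overlap},
#'   \code{identity}, \code{background}, \code{summary}, \code{pno},
#'   \code{weightedMeans}, \code{ancestral}, \code{arc}, \code{dtt},
#'   \code{ppca}, \code{manova}, \code{excluded}, \code{filterReport},
#'   \code{log}
#' @export
runPipeline <- function(stack, occurrences, tree, clades, groups = NULL,
                        config = runConfig(), outDir = NULL) {
  t0 <- as.numeric(Sys.time())
  log <- list()
  checkUltrametric(tree)
  if (!setequal(names(occurrences), tree$tip.label))
    stop("occurrence species and tree tips disagree")

  # -- occurrences: validate, thin, apply the modeling minimum ------------
  occurrences <- lapply(occurrences, function(o) {
    validateOccurrences(o, stack)
    thinOccurrences(o, config$thinDist)
  })
  counts <- vapply(occurrences, nOcc, integer(1))
  excluded <- names(counts)[counts < config$minOccurrences]
  for (sp in excluded)
    message("species '", sp, "' has ", counts[sp], " occurrence(s) (< ",
            config$minOccurrences, "): excluded from niche analyses")
  modeled <- setdiff(names(occurrences), excluded)
  if (length(modeled) < 2L) stop("fewer than two species remain after exclusion")
  prunedTree <- if (length(excluded) > 0)
    ape::drop.tip(tree, excluded) else tree
  log <- .stageLog(log, "occurrences", t0, excluded = excluded)

  # -- variable decorrelation --------------------------------------------
  fv <- filterVariables(stack, config$rThreshold,
                        priority = if (is.null(config$priority))
                          envVariables(stack) else config$priority)
  stack <- fv$stack
  log <- .stageLog(log, "filter-variables", t0,
                   retained = envVariables(stack))

  # -- niche models and AUC ----------------------------------------------
  models <- list()
  auc <- list()
  for (sp in modeled) {
    models[[sp]] <- fitMaxent(stack, occurrences[[sp]], beta = config$beta,
                              maxIter = config$maxIter,
                              minOccurrences = config$minOccurrences)
    auc[[sp]] <- evaluateAUC(stack, occurrences[[sp]],
                             nReplicates = config$aucReplicates,
                             trainFrac = config$trainFrac,
                             gate = config$aucGate,
                             seed = deriveSeed(config$seed, paste0("auc:", sp)),
                             beta = config$beta, maxIter = config$maxIter,
                             minOccurrences = 2)
  }
  log <- .stageLog(log, "enm", t0,
                   meanAUC = round(mean(vapply(auc, `[[`, numeric(1), "meanAUC")), 4))

  # -- overlap and randomization tests -----------------------------------
  overlap <- nicheOverlap(models, surface = config$surface)
  pairs <- enumerateCladePairs(clades[modeled])
  identity <- list()
  background <- list()
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$speciesA[k]; b <- pairs$speciesB[k]
    key <- paste(a, b, sep = "|")
    identity[[key]] <- identityTest(
      stack, occurrences[[a]], occurrences[[b]], metric = config$metric,
      nReplicates = config$testReplicates, conf = config$conf,
      seed = deriveSeed(config$seed, paste0("identity:", key)),
      surface = config$surface, beta = config$beta, maxIter = config$maxIter,
      minOccurrences = 2)
    background[[paste0(key, "|fwd")]] <- backgroundTest(
      stack, occurrences[[a]], occurrences[[b]], direction = "A->B",
      metric = config$metric, nReplicates = config$testReplicates,
      conf = config$conf, buffer = config$buffer,
      seed = deriveSeed(config$seed, paste0("background:", key)),
      surface = config$surface, beta = config$beta, maxIter = config$maxIter,
      minOccurrences = 2)
    if (identical(config$testDirections, "both"))
      background[[paste0(key, "|rev")]] <- backgroundTest(
        stack, occurrences[[b]], occurrences[[a]], direction = "B->A",
        metric = config$metric, nReplicates = config$testReplicates,
        conf = config$conf, buffer = config$buffer,
        seed = deriveSeed(config$seed, paste0("background-rev:", key)),
        surface = config$surface, beta = config$beta, maxIter = config$maxIter,
        minOccurrences = 2)
  }
  summary <- list(
    identity = summarizeWithinClade(identity, clades),
    background = summarizeWithinClade(background, clades))
  log <- .stageLog(log, "randomization-tests", t0, nPairs = nrow(pairs))

  # -- PNO, weighted means, ancestral tolerances -------------------------
  vars <- envVariables(stack)
  pno <- list()
  for (v in vars)
    pno[[v]] <- lapply(models, computePNO, stack = stack, variable = v,
                       nBins = config$pnoBins, surface = config$surface)
  weightedMeans <- vapply(vars, function(v)
    vapply(pno[[v]], pnoWeightedMean, numeric(1)), numeric(length(modeled)))
  rownames(weightedMeans) <- modeled
  ancestral <- lapply(vars, function(v)
    ancestralTolerance(prunedTree, pno[[v]], nSamples = config$atSamples,
                       seed = deriveSeed(config$seed, paste0("at:", v))))
  names(ancestral) <- vars
  log <- .stageLog(log, "pno", t0)

  # -- ARC, DTT/MDI -------------------------------------------------------
  arc <- ageRangeCorrelation(prunedTree, overlap, metric = config$metric,
                             weighting = config$arcWeighting,
                             nPermutations = config$arcPermutations,
                             conf = config$conf,
                             seed = deriveSeed(config$seed, "arc"))
  dtt <- lapply(vars, function(v)
    mdi(prunedTree, weightedMeans[, v], nSims = config$dttSims,
        conf = config$conf, seed = deriveSeed(config$seed, paste0("dtt:", v))))
  names(dtt) <- vars
  log <- .stageLog(log, "arc-dtt", t0, arcSlope = round(arc@slope, 5))

  # -- multivariate -------------------------------------------------------
  ppca <- phyloPCA(prunedTree, weightedMeans, mode = "corr")
  manova <- NULL
  if (!is.null(groups)) {
    gm <- droplevels(as.factor(groups[modeled]))
    k <- min(config$nComponents, ncol(ppca@scores),
             length(modeled) - nlevels(gm) - 1L)
    if (any(table(gm) < 2L) || k < 1L) {
      message("MANOVA skipped: a group has fewer than two modeled species")
    } else {
      manova <- phyloMANOVA(prunedTree, ppca@scores[, seq_len(k), drop = FALSE],
                            groups[modeled], nSims = config$manovaSims,
                            seed = deriveSeed(config$seed, "manova"))
    }
  }
  log <- .stageLog(log, "multivariate", t0)

  result <- list(models = models, auc = auc, overlap = overlap,
                 identity = identity, background = background,
                 summary = summary, pno = pno, weightedMeans = weightedMeans,
                 ancestral = ancestral, arc = arc, dtt = dtt, ppca = ppca,
                 manova = manova, excluded = excluded,
                 filterReport = fv$report, log = log)
  if (!is.null(outDir)) .writePipelineOutputs(result, config, outDir)
  result
}

.writePipelineOutputs <- function(result, config, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(outDir, f), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE)
  ov <- result$overlap
  utils::write.table(ov@D, file.path(outDir, "overlap_D.tsv"), sep = "\t",
                     quote = FALSE)
  utils::write.table(ov@I, file.path(outDir, "overlap_I.tsv"), sep = "\t",
                     quote = FALSE)
  tests <- do.call(rbind, lapply(c(result$identity, result$background),
    function(r) data.frame(test = r@test, speciesA = r@speciesA,
                           speciesB = r@speciesB, direction = r@direction,
                           observedD = r@observed["D"],
                           observedI = r@observed["I"],
                           verdict = r@verdict, p = r@pValue)))
  wt(tests, "tests.tsv")
  wm <- data.frame(species = rownames(result$weightedMeans),
                   result$weightedMeans, check.names = FALSE)
  wt(wm, "pno_weighted_means.tsv")
  wt(result$arc@nodes, "arc_nodes.tsv")
  for (v in names(result$dtt)) {
    d <- result$dtt[[v]]
    wt(data.frame(time = d@times, observed = d@observed, simMean = d@simMean,
                  lower = d@lower, upper = d@upper),
       sprintf("dtt_%s.tsv", v))
  }
  sc <- data.frame(species = rownames(result$ppca@scores),
                   result$ppca@scores, check.names = FALSE)
  wt(sc, "ppca_scores.tsv")
  manifest <- list(
    settings = config,
    excluded = result$excluded,
    mdi = lapply(result$dtt, methods::slot, "mdi"),
    arc = list(slope = result$arc@slope, intercept = result$arc@intercept,
               p = result$arc@pValue))
  if (!is.null(result$manova))
    manifest$manova <- list(F = result$manova@F, df1 = result$manova@df1,
                            df2 = result$manova@df2, p = result$manova@pValue)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outDir)
}
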