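# PNO profiles, weighted means, ancestral tolerances, age-range correlation.

test_that("PNO binning matches the hand-worked example", {
  # suitability (0.5, 0.3, 0.2) on cells with variable values (10, 10, 20),
  # bins [5,15) and [15,25) -> masses (0.8, 0.2)
  st <- makeStack(list(v = matrix(c(10, 10, 20), 1, 3)))
  pr <- computePNO(c(0.5, 0.3, 0.2), st, "v", breaks = c(5, 15, 25))
  expect_equal(pr@mass, c(0.8, 0.2))
  expect_equal(pnoMidpoints(pr), c(10, 20))
})

test_that("PNO mass is conserved and non-negative for fitted models", {
  ds <- simulateDataset(nSpecies = 4, nClades = 2, nRows = 12, nOcc = 12, seed = 121)
  for (sp in ds$tree$tip.label) {
    m <- fitMaxent(ds$stack, ds$occurrences[[sp]])
    for (v in envVariables(ds$stack)) {
      pr <- computePNO(m, ds$stack, v, nBins = 50)
      expect_equal(sum(pr@mass), 1, tolerance = 1e-12)
      expect_true(all(pr@mass >= 0))
      expect_equal(length(pr@mass), 50)
    }
  }
})

test_that("uniform suitability over evenly spread values is roughly flat", {
  st <- makeStack(list(v = matrix(seq(0, 99.9, length.out = 100), 10)))
  pr <- computePNO(rep(0.01, 100), st, "v", nBins = 10)
  expect_equal(pr@mass, rep(0.1, 10), tolerance = 1e-9)
})

test_that("a constant variable degenerates to one bin with a warning", {
  st <- makeStack(list(v = matrix(7, 3, 3)))
  expect_warning(pr <- computePNO(rep(1 / 9, 9), st, "v"), "constant")
  expect_equal(pr@mass, 1)
  expect_equal(pnoWeightedMean(pr), 7)
})

test_that("PNO weighted means match hand arithmetic", {
  mk <- function(edges, mass) new("PNOProfile", species = "s", variable = "v",
                                  edges = edges, mass = mass)
  expect_equal(pnoWeightedMean(mk(c(5, 15, 25, 35), c(0.25, 0.5, 0.25))), 20)
  expect_equal(pnoWeightedMean(mk(c(5, 15, 25), c(0.8, 0.2))), 12)
  expect_equal(pnoWeightedMean(mk(c(0, 2, 4), c(0, 1))), 3)
})

test_that("halving bin widths moves the weighted mean by less than a bin width", {
  ds <- simulateDataset(nSpecies = 3, nClades = 2, nRows = 15, nOcc = 15, seed = 122)
  m <- fitMaxent(ds$stack, ds$occurrences[[1]])
  v <- "env1"
  w50 <- pnoWeightedMean(computePNO(m, ds$stack, v, nBins = 50))
  w100 <- pnoWeightedMean(computePNO(m, ds$stack, v, nBins = 100))
  rng <- range(envValues(ds$stack, v))
  expect_lt(abs(w100 - w50), diff(rng) / 50)
})

test_that("degenerate profiles collapse ancestral tolerance to plain BM states", {
  tr <- treeABC()
  mk <- function(x, sp) new("PNOProfile", species = sp, variable = "v",
                            edges = c(x - 0.5, x + 0.5), mass = 1)
  profs <- list(A = mk(0, "A"), B = mk(2, "B"), C = mk(6, "C"))
  at <- ancestralTolerance(tr, profs, nSamples = 25, seed = 123)
  expect_equal(ncol(at@samples), 25)
  rec <- bmAncestralStates(tr, c(A = 0, B = 2, C = 6))
  for (s in 1:25) expect_equal(unname(at@samples[, s]), unname(rec))
  # two-tip symmetric case: root constant at the midpoint
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  at2 <- ancestralTolerance(t2, list(A = mk(0, "A"), B = mk(10, "B")),
                            nSamples = 10, seed = 124)
  expect_true(all(at2@samples == 5))
})

test_that("ancestral tolerance recovers the simulated root optimum", {
  # tip optima evolve under BM; PNO profiles built from the analytic truth
  st <- simulateEnvStack("e", nRows = 25, autocorrLength = 2,
                         targetCorr = matrix(1, 1, 1), seed = 125)
  tr <- simulateTree(8, seed = 126)
  rootMu <- 50
  set.seed(127)
  roots <- vapply(1:100, function(r) {
    niche <- evolveNiches(tr, c(e = rootMu), c(e = 12), rateBM = 200)
    profs <- lapply(tr$tip.label, function(sp) {
      s <- trueSuitability(st, niche$optima[sp, ], c(e = 12))
      computePNO(s / sum(s), st, "e", nBins = 50, species = sp)
    })
    names(profs) <- tr$tip.label
    at <- ancestralTolerance(tr, profs, nSamples = 30)
    at@summary$mean[at@summary$node == 9]
  }, numeric(1))
  expect_lt(abs(mean(roots) - rootMu), 2 * sd(roots))
})

test_that("missing tip profiles are an error", {
  tr <- treeABC()
  expect_error(ancestralTolerance(tr, list(A = NULL), nSamples = 5),
               "no PNO profile")
})

test_that("ARC node overlaps follow the weighting rule on the 3-tip example", {
  tr <- treeABC()
  M <- matrix(1, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  M["A", "C"] <- M["C", "A"] <- 0.2
  M["B", "C"] <- M["C", "B"] <- 0.4
  M["A", "B"] <- M["B", "A"] <- 0.9
  o <- arcNodeOverlaps(tr, M, weighting = "ft")
  expect_equal(unname(o["4"]), 0.3)     # root: (0.5*0.2 + 0.5*0.4) / 1
  expect_equal(unname(o["5"]), 0.9)     # AB node: its single pair
})

test_that("'mean' weighting equals the plain average of cross-clade pairs", {
  tr <- simulateTree(6, seed = 128)
  set.seed(129)
  M <- matrix(runif(36), 6, 6); M <- (M + t(M)) / 2; diag(M) <- 1
  dimnames(M) <- list(tr$tip.label, tr$tip.label)
  arc <- ageRangeCorrelation(tr, M, weighting = "mean", nPermutations = 0)
  # enumeration oracle
  mr <- ape::mrca(tr)
  for (k in seq_len(nrow(arc@nodes))) {
    node <- arc@nodes$node[k]
    vals <- c()
    for (i in 1:5) for (j in (i + 1):6)
      if (mr[i, j] == node) vals <- c(vals, M[i, j])
    expect_equal(arc@nodes$overlap[k], mean(vals))
  }
})

test_that("a constant overlap matrix gives slope zero and no outliers", {
  tr <- simulateTree(7, seed = 130)
  M <- matrix(0.4, 7, 7); diag(M) <- 1
  dimnames(M) <- list(tr$tip.label, tr$tip.label)
  arc <- ageRangeCorrelation(tr, M, nPermutations = 0)
  expect_equal(arc@slope, 0, tolerance = 1e-12)
  expect_true(all(arc@nodes$flag == ""))
})

test_that("regression is refused below three internal nodes", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  M <- matrix(1, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(ageRangeCorrelation(tr, M, nPermutations = 0), "3 internal")
})

test_that("permutation p is small for strongly age-structured overlap", {
  tr <- simulateTree(8, seed = 131)
  age <- ape::branching.times(tr)
  # build overlap declining deterministically with MRCA age
  mr <- ape::mrca(tr)
  M <- matrix(1, 8, 8, dimnames = list(tr$tip.label, tr$tip.label))
  for (i in 1:7) for (j in (i + 1):8)
    M[i, j] <- M[j, i] <- 1 - age[as.character(mr[i, j])]
  arc <- ageRangeCorrelation(tr, M, nPermutations = 200, seed = 132)
  expect_lt(arc@slope, 0)
  expect_lt(arc@pValue, 0.05)
})
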