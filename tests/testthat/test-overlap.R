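# Overlap metrics, their invariants, and the randomization tests.

test_that("Schoener's D and Warren's I hand values and limits", {
  expect_equal(schoenerD(c(0.5, 0.5), c(0.5, 0.5)), 1)
  expect_equal(warrenI(c(0.5, 0.5), c(0.5, 0.5)), 1)
  expect_equal(schoenerD(c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5)), 0)
  expect_equal(warrenI(c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5)), 0)
  expect_equal(schoenerD(c(0.6, 0.4), c(0.4, 0.6)), 0.8)
  expect_equal(warrenI(c(1, 0), c(0.5, 0.5)), sqrt(2) / 2, tolerance = 1e-12)
})

test_that("unnormalized inputs are rejected", {
  expect_error(schoenerD(c(0.6, 0.6), c(0.5, 0.5)), "normalized")
  expect_error(warrenI(c(0.5, 0.5), c(0.2, 0.2)), "normalized")
})

test_that("I dominates D; both are symmetric and relabeling-invariant", {
  set.seed(101)
  for (r in 1:200) {
    n <- sample(2:30, 1)
    p <- rgamma(n, 0.5); p <- p / sum(p)
    q <- rgamma(n, 0.5); q <- q / sum(q)
    D <- schoenerD(p, q); I <- warrenI(p, q)
    expect_gte(I, D - 1e-12)
    expect_true(D >= 0 && I <= 1 + 1e-12)
    expect_equal(D, schoenerD(q, p))
    expect_equal(I, warrenI(q, p))
    perm <- sample(n)
    expect_equal(D, schoenerD(p[perm], q[perm]))
    expect_equal(I, warrenI(p[perm], q[perm]))
  }
})

test_that("overlap matrices satisfy their structural invariants", {
  ds <- simulateDataset(nSpecies = 5, nClades = 2, nRows = 12, nOcc = 15, seed = 102)
  models <- lapply(ds$occurrences, function(o) fitMaxent(ds$stack, o))
  ov <- nicheOverlap(models)
  expect_true(validObject(ov))
  expect_equal(diag(ov@D), setNames(rep(1, 5), ds$tree$tip.label))
  expect_true(all(ov@I - ov@D >= -1e-12))
  expect_equal(ov@D, t(ov@D))
})

test_that("identical occurrence sets give observed overlap 1 and no rejection", {
  st <- simulateEnvStack(c("a", "b"), nRows = 10, autocorrLength = 1,
                         targetCorr = 0, seed = 103)
  occ <- sampleOccurrences(st, c(a = 50, b = 50), c(a = 15, b = 15), 12, seed = 104)
  occB <- methods::initialize(occ, species = "twin")
  res <- identityTest(st, occ, occB, nReplicates = 30, seed = 105)
  expect_equal(unname(res@observed["D"]), 1, tolerance = 1e-9)
  expect_identical(res@verdict, "identity-not-rejected")
  expect_equal(nrow(res@null), 30)
})

test_that("disjoint niche optima lead to identity rejection", {
  st <- simulateEnvStack(c("a", "b"), nRows = 15, autocorrLength = 1,
                         targetCorr = 0, seed = 106)
  oA <- sampleOccurrences(st, c(a = 5, b = 5), c(a = 5, b = 5), 20,
                          species = "lo", seed = 107)
  oB <- sampleOccurrences(st, c(a = 95, b = 95), c(a = 5, b = 5), 20,
                          species = "hi", seed = 108)
  res <- identityTest(st, oA, oB, nReplicates = 50, seed = 109)
  expect_identical(res@verdict, "identity-rejected")
  expect_lt(res@observed["D"], res@lower["D"])
})

test_that("a species tested against its own occurrence-cell background is n.s.", {
  st <- simulateEnvStack(c("a", "b"), nRows = 12, autocorrLength = 1,
                         targetCorr = 0, seed = 110)
  # occurrences at 15 distinct cell centers
  set.seed(111)
  cells <- sample(which(envMask(st)), 15)
  occ <- makeOcc(envCellCenters(st)[match(cells, which(envMask(st))), ])
  # background = exactly the species' own occupied cells: the null process
  # regenerates the observed situation, so no signal either way
  bg <- matrix(FALSE, 12, 12)
  bg[cells] <- TRUE
  res <- backgroundTest(st, occ, occ, backgroundB = bg, nReplicates = 50,
                        seed = 112)
  expect_identical(res@verdict, "n.s.")
})

test_that("background smaller than the pseudolocality count is an error", {
  st <- simulateEnvStack(c("a", "b"), nRows = 10, autocorrLength = 0,
                         targetCorr = 0, seed = 113)
  occ <- sampleOccurrences(st, c(a = 50, b = 50), c(a = 20, b = 20), 10, seed = 114)
  bg <- matrix(FALSE, 10, 10); bg[1:3] <- TRUE
  expect_error(backgroundTest(st, occ, occ, backgroundB = bg, seed = 1),
               "pseudolocalities")
})

test_that("the background mask covers the occurrences plus the buffer", {
  st <- simulateEnvStack("e", nRows = 20, autocorrLength = 0,
                         targetCorr = matrix(1, 1, 1), seed = 115)
  occ <- makeOcc(cbind(c(5.5, 9.5, 7.5), c(5.5, 5.5, 9.5)))
  bg <- backgroundMask(st, occ, buffer = 2)
  idx <- cellIndexOf(st, occPoints(occ))
  expect_true(all(bg[idx]))
  # cells far outside the buffered hull are excluded
  expect_false(bg[cellIndexOf(st, c(0.5, 19.5))])
  # a larger buffer can only grow the background
  bg2 <- backgroundMask(st, occ, buffer = 4)
  expect_true(all(bg2[bg]))
  expect_gt(sum(bg2), sum(bg))
})

test_that("clade pair enumeration and verdict percentages follow the counting rules", {
  clades <- setNames(rep(c("p", "n", "s"), times = c(6, 8, 7)),
                     paste0("sp", 1:21))
  pairs <- enumerateCladePairs(clades)
  expect_equal(as.integer(table(pairs$clade)[c("p", "n", "s")]),
               c(choose(6, 2), choose(8, 2), choose(7, 2)))
  expect_equal(nrow(pairs), 64)
  # verdict summary: flag 17 of the n-clade pairs as conservatism
  np <- pairs[pairs$clade == "n", ]
  results <- data.frame(speciesA = pairs$speciesA, speciesB = pairs$speciesB,
                        verdict = "n.s.", stringsAsFactors = FALSE)
  results$verdict[match(paste(np$speciesA, np$speciesB),
                        paste(results$speciesA, results$speciesB))[1:17]] <- "conservatism"
  sm <- summarizeWithinClade(results, clades)
  row <- sm[sm$clade == "n" & sm$verdict == "conservatism", ]
  expect_equal(row$count, 17)
  expect_equal(row$nPairs, 28)
  expect_equal(row$percent, 61)
  expect_equal(sm[sm$clade == "p" & sm$verdict == "conservatism", "count"], 0)
  expect_equal(sm[sm$clade == "p" & sm$verdict == "conservatism", "percent"], 0)
})

test_that("a species without clade label is an error", {
  res <- data.frame(speciesA = "a", speciesB = "b", verdict = "n.s.")
  expect_error(summarizeWithinClade(res, c(a = "x")), "without clade label")
})

test_that("directions are tracked and duplicated directions count once", {
  clades <- c(a = "c1", b = "c1")
  res <- data.frame(speciesA = c("a", "b"), speciesB = c("b", "a"),
                    verdict = c("conservatism", "conservatism"))
  sm <- summarizeWithinClade(res, clades)
  expect_equal(sm[sm$verdict == "conservatism", "count"], 1)
  expect_equal(sm[sm$verdict == "conservatism", "percent"], 100)
})
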