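# Maximum-entropy niche model: limits, KKT property, AUC, MTP, clade maps.

# 2x2 stack with a binary-looking variable: cells (by column-major order of
# the mask) carry values 1, 1, 0, 0.
binaryStack <- function() {
  makeStack(list(f = matrix(c(1, 1, 0, 0), 2, 2)))
}

# occurrences at the centers of given mask-order cell positions
occAtCells <- function(stack, pos, species = "sp", times = 1) {
  centers <- envCellCenters(stack)
  makeOcc(centers[rep(pos, times), , drop = FALSE], species)
}

test_that("an empty feature set yields the uniform distribution", {
  set.seed(61)
  st <- simulateEnvStack("e", nRows = 5, autocorrLength = 0,
                         targetCorr = matrix(1, 1, 1), seed = 61)
  occ <- occAtCells(st, c(1, 3, 7, 9, 12))
  m <- fitMaxent(st, occ, features = character(0))
  p <- m@raw[!is.na(m@raw)]
  expect_equal(p, rep(1 / 25, 25), tolerance = 1e-12)
  expect_equal(m@entropy, log(25), tolerance = 1e-10)
  # uniform model has logistic = tau everywhere
  expect_equal(unique(round(m@logistic[!is.na(m@logistic)], 10)), 0.5)
})

test_that("with beta = 0 the fit matches the constraint: mass splits over presence cells", {
  st <- binaryStack()
  occ <- occAtCells(st, c(1, 2), times = 3)       # 6 presences, all on f = 1 cells
  m <- suppressWarnings(fitMaxent(st, occ, beta = 0, maxIter = 3000,
                                  tol = 1e-12, minOccurrences = 2))
  p <- m@raw[!is.na(m@raw)]
  expect_equal(p[1:2], c(0.5, 0.5), tolerance = 0.01)
  expect_lt(max(p[3:4]), 0.01)
})

test_that("every fitted model satisfies the KKT slack |E_p f - presence mean| <= beta_j", {
  for (s in 1:5) {
    st <- simulateEnvStack(c("a", "b"), nRows = 12, autocorrLength = 1,
                           targetCorr = 0.3, seed = 70 + s)
    set.seed(80 + s)
    v <- envValues(st)
    opt <- setNames(v[sample(nrow(v), 1), ], c("a", "b"))
    occ <- sampleOccurrences(st, opt, c(a = 20, b = 20), 15, seed = 90 + s)
    # tight convergence: the KKT bound is a property of the exact minimizer
    m <- fitMaxent(st, occ, beta = 1, tol = 1e-11, maxIter = 5000)
    expect_true(m@converged)
    # recompute both sides from scratch
    E <- envValues(st)
    Z <- sweep(sweep(E, 2, m@featureCenter), 2, m@featureScale, "/")
    F <- cbind(Z, Z^2)
    p <- m@raw[!is.na(m@raw)]
    pos <- match(cellIndexOf(st, occPoints(occ)), which(envMask(st)))
    slack <- abs(colSums(F * p) - colMeans(F[pos, , drop = FALSE]))
    expect_true(all(slack <= unname(m@betaJ) + 1e-6))
  }
})

test_that("the optimizer's objective trace is non-increasing and raw sums to 1", {
  st <- simulateEnvStack(c("a", "b"), nRows = 10, autocorrLength = 0,
                         targetCorr = 0, seed = 62)
  occ <- sampleOccurrences(st, c(a = 40, b = 60), c(a = 15, b = 15), 12, seed = 63)
  m <- fitMaxent(st, occ)
  expect_true(all(diff(m@objective) <= 1e-12))
  expect_equal(sum(m@raw, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_true(all(m@logistic[!is.na(m@logistic)] >= 0 &
                  m@logistic[!is.na(m@logistic)] <= 1))
})

test_that("fewer than five occurrences are refused with an exclusion status", {
  st <- binaryStack()
  occ <- occAtCells(st, c(1, 2, 3, 4))
  err <- tryCatch(fitMaxent(st, occ), error = identity)
  expect_s3_class(err, "enmTooFewOccurrences")
  expect_match(conditionMessage(err), "excluded from niche analyses")
})

test_that("beta = 0 fit matches a direct constrained-entropy optimization on a tiny grid", {
  # Oracle: maximize entropy of p subject to E_p[f] = presence mean
  # (helper maxentEntropyOracle: dual BFGS + Newton polish), independent of
  # the package's coordinate descent on the regularized likelihood.
  st <- simulateEnvStack(c("a", "b"), nRows = 4, autocorrLength = 0,
                         targetCorr = 0, seed = 64)     # 16 cells
  occ <- occAtCells(st, c(1, 4, 6, 6, 11), species = "sp")
  m <- suppressWarnings(fitMaxent(st, occ, beta = 0, maxIter = 20000, tol = 1e-14))
  E <- envValues(st)
  Z <- sweep(sweep(E, 2, m@featureCenter), 2, m@featureScale, "/")
  F <- cbind(Z, Z^2)
  pos <- match(cellIndexOf(st, occPoints(occ)), which(envMask(st)))
  b <- colMeans(F[pos, , drop = FALSE])
  pOracle <- maxentEntropyOracle(F, b)
  expect_lt(max(abs(m@raw[!is.na(m@raw)] - pOracle)), 1e-5)
})

test_that("rank AUC handles perfect separation and total ties", {
  expect_equal(rankAUC(c(0.9, 0.8), c(0.1, 0.2)), 1)
  expect_equal(rankAUC(c(0.5, 0.5, 0.5), rep(0.5, 10)), 0.5)
  expect_equal(rankAUC(0.2, c(0.1, 0.3)), 0.5)
})

test_that("replicate AUC is high for a strong synthetic niche signal", {
  st <- simulateEnvStack(c("a", "b"), nRows = 20, autocorrLength = 2,
                         targetCorr = 0.2, seed = 65)
  occ <- sampleOccurrences(st, c(a = 50, b = 50), c(a = 8, b = 8), 30, seed = 66)
  rep <- evaluateAUC(st, occ, nReplicates = 10, trainFrac = 0.59, seed = 67)
  expect_equal(nrow(rep$replicates), 10)
  expect_true(all(rep$replicates$auc >= 0 & rep$replicates$auc <= 1))
  expect_gte(rep$meanAUC, 0.85)
  expect_true(rep$pass)
  # 59/41 split sizes
  expect_equal(lengths(rep$splits), rep(round(0.59 * 30), 10))
})

test_that("too few points to split is an error", {
  st <- binaryStack()
  expect_error(evaluateAUC(st, occAtCells(st, 1), seed = 1), "too few|split")
})

test_that("MTP thresholding keeps exactly the cells at or above the minimum presence value", {
  st <- simulateEnvStack(c("a", "b"), nRows = 10, autocorrLength = 1,
                         targetCorr = 0, seed = 68)
  occ <- sampleOccurrences(st, c(a = 30, b = 70), c(a = 12, b = 12), 10, seed = 69)
  m <- fitMaxent(st, occ)
  pos <- validateOccurrences(occ, st)
  expect_equal(m@mtp, min(m@logistic[pos]))
  bin <- applyMTP(m)
  expect_true(all(bin[pos]))
  expect_identical(bin, m@logistic >= m@mtp)
  # thresholding at the maximum presence value keeps only top cells
  best <- occAtCells(st, which.max(m@logistic[which(envMask(st))]), times = 5)
  bin2 <- applyMTP(m, best, st)
  expect_identical(bin2, m@logistic >= max(m@logistic, na.rm = TRUE))
})

test_that("cumulative clade maps add logistic surfaces and stay bounded", {
  st <- simulateEnvStack(c("a", "b"), nRows = 8, autocorrLength = 0,
                         targetCorr = 0, seed = 71)
  o1 <- sampleOccurrences(st, c(a = 30, b = 30), c(a = 15, b = 15), 8, seed = 72)
  o2 <- sampleOccurrences(st, c(a = 70, b = 70), c(a = 15, b = 15), 8, seed = 73)
  m1 <- fitMaxent(st, o1); m2 <- fitMaxent(st, o2)
  expect_identical(cumulativeCladeMap(list(m1)), m1@logistic)
  expect_equal(cumulativeCladeMap(list(m1, m1)), 2 * m1@logistic)
  cm <- cumulativeCladeMap(list(m1, m2, m1))
  expect_lte(max(cm, na.rm = TRUE), 3)
  st2 <- simulateEnvStack("a", nRows = 4, autocorrLength = 0,
                          targetCorr = matrix(1, 1, 1), seed = 74)
  o3 <- occAtCells(st2, c(1, 2, 3, 4, 5))
  expect_error(cumulativeCladeMap(list(m1, fitMaxent(st2, o3))), "different grids")
})
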