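# Statistical structure of the synthetic-data generators.

test_that("all four generators are deterministic under a fixed seed", {
  s1 <- simulateEnvStack(nRows = 12, seed = 3)
  s2 <- simulateEnvStack(nRows = 12, seed = 3)
  expect_identical(envValues(s1), envValues(s2))
  t1 <- simulateTree(9, seed = 4); t2 <- simulateTree(9, seed = 4)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  ro <- c(env1 = 50, env2 = 50); br <- c(env1 = 10, env2 = 10)
  n1 <- evolveNiches(t1, ro, br, rateBM = 100, seed = 5)
  n2 <- evolveNiches(t1, ro, br, rateBM = 100, seed = 5)
  expect_identical(n1$optima, n2$optima)
  o1 <- sampleOccurrences(s1, c(env1 = 50, env2 = 50, env3 = 50),
                          c(env1 = 15, env2 = 15, env3 = 15), 25, seed = 6)
  o2 <- sampleOccurrences(s1, c(env1 = 50, env2 = 50, env3 = 50),
                          c(env1 = 15, env2 = 15, env3 = 15), 25, seed = 6)
  expect_identical(occPoints(o1), occPoints(o2))
})

test_that("simulated layers hit the target inter-variable correlation", {
  target <- matrix(c(1, 0.6, 0.2, 0.6, 1, 0.4, 0.2, 0.4, 1), 3, 3)
  st <- simulateEnvStack(c("a", "b", "c"), nRows = 100, nCols = 100,
                         autocorrLength = 0, targetCorr = target, seed = 11)
  got <- cor(envValues(st))
  expect_lt(max(abs(got - target)), 0.1)
  # identity target: independent layers
  st0 <- simulateEnvStack(c("a", "b", "c"), nRows = 100, nCols = 100,
                          autocorrLength = 0, targetCorr = 0, seed = 12)
  r0 <- cor(envValues(st0))
  expect_lt(max(abs(r0[upper.tri(r0)])), 0.1)
})

test_that("spatial smoothing preserves the target correlation and adds autocorrelation", {
  st <- simulateEnvStack(c("a", "b"), nRows = 60, nCols = 60,
                         autocorrLength = 3, targetCorr = 0.5, seed = 13)
  expect_lt(abs(cor(envValues(st))[1, 2] - 0.5), 0.12)
  # neighbouring cells are more alike than distant ones
  g <- envGrid(st, "a")
  lag1 <- cor(as.vector(g[, -1]), as.vector(g[, -60]))
  lag20 <- cor(as.vector(g[, -(1:20)]), as.vector(g[, -(41:60)]))
  expect_gt(lag1, 0.8)
  expect_gt(lag1, lag20 + 0.2)
})

test_that("a non-PSD correlation target is rejected", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(simulateEnvStack(c("a", "b", "c"), targetCorr = bad, seed = 1),
               "positive semidefinite")
})

test_that("pure-birth trees are binary, ultrametric, rescaled to depth 1", {
  for (n in c(2, 5, 17)) {
    tr <- simulateTree(n, seed = n)
    expect_equal(ape::Ntip(tr), n)
    expect_equal(tr$Nnode, n - 1L)                 # rooted binary
    expect_equal(checkUltrametric(tr), 1, tolerance = 1e-9)
  }
  # n = 2: single root node at age 1
  t2 <- simulateTree(2, seed = 1)
  expect_equal(unname(ape::branching.times(t2)), 1)
})

test_that("unscaled Yule depth matches its analytic expectation", {
  # E[depth] = sum_{k=2}^{n} 1/(k * lambda) for the forward Yule process
  n <- 6; lambda <- 2
  expected <- sum(1 / (2:n * lambda))
  depths <- vapply(1:500, function(s)
    attr(simulateTree(n, lambda, seed = 1000 + s), "rawDepth"), numeric(1))
  se <- sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - expected), 3.5 * se)
})

test_that("BM niche evolution follows the variance law; zero rate is constant", {
  tr <- simulateTree(4, seed = 21)                 # depth 1
  ro <- c(v = 0); br <- c(v = 1)
  expect_equal(unname(evolveNiches(tr, ro, br, rateBM = 0, seed = 1)$optima[, 1]),
               rep(0, 4))
  # across replicate runs, Var(tip) = rate * depth
  rate <- 25
  set.seed(22)
  tips <- replicate(1000, evolveNiches(tr, ro, br, rateBM = rate,
                                       seed = NULL)$optima["t1", 1])
  expect_lt(abs(var(tips) / (rate * 1) - 1), 0.10)
})

test_that("OU niches reach the stationary variance around the clade optimum", {
  tr <- ape::read.tree(text = "(A:1,B:1);")       # root = clade MRCA
  clades <- c(A = "c1", B = "c1"); regimes <- c(c1 = "OU")
  rate <- 400; alpha <- 20                         # stationary var = rate / (2 alpha)
  set.seed(23)
  tips <- replicate(1500, evolveNiches(tr, c(v = 50), c(v = 10), rateBM = rate,
                                       regimes = regimes, clades = clades,
                                       alpha = alpha)$optima["A", 1])
  expect_lt(abs(mean(tips) - 50), 0.5)
  expect_lt(abs(var(tips) / (rate / (2 * alpha)) - 1), 0.15)
})

test_that("conservatism (OU) keeps sister tips closer than divergence (BM)", {
  tr <- simulateTree(8, seed = 24)
  clades <- setNames(rep("c1", 8), tr$tip.label)
  sisterGap <- function(regime, s) {
    fit <- evolveNiches(tr, c(v = 50), c(v = 10), rateBM = 400,
                        regimes = c(c1 = regime), clades = clades,
                        alpha = 10, seed = s)
    mean(dist(fit$optima))
  }
  set.seed(25)
  gapOU <- vapply(1:40, function(s) sisterGap("OU", 300 + s), numeric(1))
  gapBM <- vapply(1:40, function(s) sisterGap("BM", 300 + s), numeric(1))
  expect_lt(mean(gapOU), mean(gapBM))
  expect_gt(mean(gapBM) - mean(gapOU),
            2 * sqrt(var(gapOU) / 40 + var(gapBM) / 40))
})

test_that("occurrence sampling matches the multinomial cell probabilities", {
  st <- simulateEnvStack("e", nRows = 8, nCols = 8, autocorrLength = 0,
                         targetCorr = matrix(1, 1, 1), seed = 31)
  opt <- c(e = 50); br <- c(e = 30)
  s <- trueSuitability(st, opt, br)
  p <- s / sum(s)
  occ <- sampleOccurrences(st, opt, br, 1e5, seed = 32)
  idx <- cellIndexOf(st, occPoints(occ))
  freq <- tabulate(match(idx, which(envMask(st))), nbins = length(p)) / 1e5
  se <- sqrt(p * (1 - p) / 1e5)
  expect_true(all(abs(freq - p) <= 3 * se + 1e-12))
})

test_that("degenerate suitability concentrates all points in one cell", {
  st <- simulateEnvStack("e", nRows = 6, nCols = 6, autocorrLength = 0,
                         targetCorr = matrix(1, 1, 1), seed = 33)
  v <- envValues(st)[, 1]
  best <- which.max(v)
  occ <- sampleOccurrences(st, c(e = v[best]), c(e = 1e-4), 50, seed = 34)
  idx <- unique(cellIndexOf(st, occPoints(occ)))
  expect_identical(idx, which(envMask(st))[best])
})

test_that("points fall within their sampled cells and on valid cells", {
  ds <- simulateDataset(nSpecies = 4, nClades = 2, nRows = 10, nOcc = 30, seed = 35)
  for (o in ds$occurrences) expect_silent(validateOccurrences(o, ds$stack))
})

test_that("written datasets are readable back with matching content", {
  dir <- withr::local_tempdir()
  ds <- simulateDataset(nSpecies = 4, nClades = 2, nRows = 10, nOcc = 12, seed = 36)
  writeDataset(ds, dir)
  st <- readEnvStack(file.path(dir, paste0(c("env1", "env2", "env3"), ".asc")))
  expect_equal(envValues(st), envValues(ds$stack))
  occ <- readOccurrences(file.path(dir, "occurrences.csv"))
  expect_setequal(names(occ), ds$tree$tip.label)
  tr <- ape::read.tree(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, ds$tree$tip.label)
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(truth$mu_env1[match(rownames(ds$truth$optima), truth$species)],
               unname(ds$truth$optima[, "env1"]))
})
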