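# Small deterministic fixtures built in code.

# EnvStack from explicit per-variable matrices (row 1 = north).
makeStack <- function(grids, cellsize = 1, xll = 0, yll = 0) {
  mask <- Reduce(`&`, lapply(grids, function(g) !is.na(g)))
  grids <- lapply(grids, function(g) { g[!mask] <- NA_real_; g })
  new("EnvStack", grids = grids, xll = xll, yll = yll,
      cellsize = cellsize, mask = mask)
}

makeOcc <- function(xy, species = "sp") {
  xy <- rbind(xy)
  dimnames(xy) <- list(NULL, c("x", "y"))
  new("OccurrenceSet", species = species, points = xy)
}

# Hand-written trees used across tests.
treeABC <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")
treeAB1C3 <- function() ape::read.tree(text = "((A:1,B:1):2,C:3);")
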