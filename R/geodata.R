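# Raster / occurrence IO, spatial thinning and the variable decorrelation
# filter.  Rasters use the ESRI ASCII grid dialect (NCOLS/NROWS/XLLCORNER/
# YLLCORNER/CELLSIZE/NODATA_VALUE header followed by row-major values from
# the north); occurrences are CSV with header species,x,y.

.parseAscHeader <- function(lines, path) {
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) != 2L || is.na(suppressWarnings(as.numeric(tok[2])))) break
    hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
    i <- i + 1L
    if (i >= 6L) break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("cannot parse ESRI ASCII header of '", path, "': missing ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  hdr$nodata_value <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  hdr$nHeader <- i
  hdr
}

.readAsc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- .parseAscHeader(lines, path)
  vals <- scan(text = paste(lines[-seq_len(hdr$nHeader)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols)
    stop("'", path, "': expected ", hdr$nrows * hdr$ncols,
         " cell values, found ", length(vals))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  list(grid = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cellsize = hdr$cellsize)
}

#' Read a stack of ESRI ASCII grids
#'
#' All files must share the same geometry (rows, columns, cell size and
#' origin).  The stack's validity mask is the union of the per-file nodata
#' cells: a cell flagged nodata in any layer is masked in all of them.
#'
#' @param paths character vector of .asc file paths
#' @param variables variable names (default: file basename without extension)
#' @return an [EnvStack-class]
#' @export
readEnvStack <- function(paths, variables = NULL) {
  if (length(paths) == 0L) stop("no raster files given")
  if (is.null(variables))
    variables <- sub("\\.[^.]*$", "", basename(paths))
  layers <- lapply(paths, .readAsc)
  ref <- layers[[1]]
  for (k in seq_along(layers)[-1]) {
    l <- layers[[k]]
    if (!identical(dim(l$grid), dim(ref$grid)) ||
        abs(l$cellsize - ref$cellsize) > 1e-9 * ref$cellsize ||
        abs(l$xll - ref$xll) > 1e-6 * ref$cellsize ||
        abs(l$yll - ref$yll) > 1e-6 * ref$cellsize)
      stop("grid geometry of '", paths[k], "' does not match '", paths[1], "'")
  }
  grids <- lapply(layers, `[[`, "grid")
  names(grids) <- variables
  mask <- Reduce(`&`, lapply(grids, function(g) !is.na(g)))
  grids <- lapply(grids, function(g) { g[!mask] <- NA_real_; g })
  new("EnvStack", grids = grids, xll = ref$xll, yll = ref$yll,
      cellsize = ref$cellsize, mask = mask)
}

#' Write an EnvStack as ESRI ASCII grids
#'
#' One file per variable, \code{<dir>/<variable>.asc}, values written at
#' full double precision so that a read/write round trip is exact.
#'
#' @param stack an [EnvStack-class]
#' @param dir output directory (created if needed)
#' @param nodata nodata sentinel written for masked cells
#' @return invisibly, the written file paths
#' @export
writeEnvStack <- function(stack, dir, nodata = -9999) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nr <- nrow(stack@mask); nc <- ncol(stack@mask)
  paths <- character(0)
  for (v in envVariables(stack)) {
    g <- envGrid(stack, v)
    g[is.na(g)] <- nodata
    path <- file.path(dir, paste0(v, ".asc"))
    hdr <- c(sprintf("NCOLS %d", nc), sprintf("NROWS %d", nr),
             sprintf("XLLCORNER %.17g", stack@xll),
             sprintf("YLLCORNER %.17g", stack@yll),
             sprintf("CELLSIZE %.17g", stack@cellsize),
             sprintf("NODATA_VALUE %g", nodata))
    body <- apply(g, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
    writeLines(c(hdr, body), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Map points to grid cells
#'
#' Cells are half-open, \code{[x0, x0+cs)} in x and \code{(y0-cs, y0]} in y,
#' with row 1 the northernmost row.  Returns matrix-linear cell indices
#' (column-major), or NA for points outside the extent.
#'
#' @param stack an [EnvStack-class]
#' @param xy two-column matrix of coordinates
#' @return integer vector of cell indices into the grid matrices
#' @export
cellIndexOf <- function(stack, xy) {
  xy <- rbind(xy)
  nr <- nrow(stack@mask); nc <- ncol(stack@mask); cs <- stack@cellsize
  ytop <- stack@yll + nr * cs
  col <- floor((xy[, 1] - stack@xll) / cs) + 1
  # floor realizes the convention directly: a y on an interior cell boundary
  # belongs to the cell whose top edge it is, and y = ytop maps to row 1
  row <- floor((ytop - xy[, 2]) / cs) + 1
  out <- (col - 1) * nr + row
  bad <- col < 1 | col > nc | row < 1 | row > nr | !is.finite(out)
  out[bad] <- NA_integer_
  as.integer(out)
}

#' Check occurrences against a stack
#'
#' Errors unless every point falls inside the stack extent and on a
#' non-masked cell.
#'
#' @param occ an [OccurrenceSet-class]
#' @param stack an [EnvStack-class]
#' @return invisibly, the cell index of each point
#' @export
validateOccurrences <- function(occ, stack) {
  idx <- cellIndexOf(stack, occ@points)
  if (anyNA(idx))
    stop("species '", occ@species, "': ", sum(is.na(idx)),
         " occurrence(s) fall outside the grid extent")
  if (any(!stack@mask[idx]))
    stop("species '", occ@species, "': ", sum(!stack@mask[idx]),
         " occurrence(s) fall on masked (nodata) cells")
  invisible(idx)
}

#' Read occurrence records
#'
#' Expects a CSV with header \code{species,x,y}.
#'
#' @param path CSV file
#' @return named list of [OccurrenceSet-class], one per species, in order of
#'   first appearance
#' @export
readOccurrences <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "x", "y") %in% names(d)))
    stop("occurrence file must have columns species, x, y")
  sp <- unique(d$species)
  out <- lapply(sp, function(s) {
    p <- as.matrix(d[d$species == s, c("x", "y")])
    dimnames(p) <- list(NULL, c("x", "y"))
    new("OccurrenceSet", species = s, points = p, source = path)
  })
  names(out) <- sp
  out
}

#' Write occurrence records
#' @param occList list of [OccurrenceSet-class]
#' @param path output CSV
#' @return invisibly, \code{path}
#' @export
writeOccurrences <- function(occList, path) {
  d <- do.call(rbind, lapply(occList, function(o)
    data.frame(species = o@species,
               x = o@points[, 1], y = o@points[, 2])))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Thin occurrences to a minimum separation
#'
#' Greedy pass in input order: a point is kept iff its Euclidean distance
#' (map units) to every already-kept point is at least \code{minDist}.
#' First record wins; output order is preserved.  Thinning is idempotent.
#'
#' @param occ an [OccurrenceSet-class]
#' @param minDist minimum separation in map units (>= 0)
#' @return a thinned [OccurrenceSet-class]
#' @export
thinOccurrences <- function(occ, minDist) {
  stopifnot(minDist >= 0)
  p <- occ@points
  if (minDist == 0 || nrow(p) <= 1L) return(occ)
  keep <- logical(nrow(p))
  keep[1] <- TRUE
  for (i in seq_len(nrow(p))[-1]) {
    kept <- p[keep, , drop = FALSE]
    d2 <- (kept[, 1] - p[i, 1])^2 + (kept[, 2] - p[i, 2])^2
    keep[i] <- all(d2 >= minDist^2)
  }
  methods::initialize(occ, points = p[keep, , drop = FALSE])
}

#' Decorrelate environmental variables
#'
#' Pearson correlations are computed over the non-masked cells.  Variables
#' are visited in \code{priority} order (earlier = preferred; the caller
#' encodes "extremes over averages" here) and a variable is retained iff its
#' absolute correlation with every already-retained variable does not exceed
#' \code{rThreshold}.  A zero-variance variable has undefined correlation;
#' it is treated as uncorrelated, with a warning.
#'
#' @param stack an [EnvStack-class]
#' @param rThreshold correlation threshold in \code{[0, 1]} (default 0.9)
#' @param priority ordered character vector covering all variables
#' @return list with \code{stack} (retained variables, original mask) and
#'   \code{report} (data frame of dropped variables and their blocking
#'   partner and correlation)
#' @export
filterVariables <- function(stack, rThreshold = 0.9,
                            priority = envVariables(stack)) {
  if (!setequal(priority, envVariables(stack)))
    stop("priority must cover exactly the stack's variables")
  V <- envValues(stack, priority)
  sds <- apply(V, 2L, stats::sd)
  if (any(sds == 0))
    warning("constant variable(s) with undefined correlation, treated as uncorrelated: ",
            paste(priority[sds == 0], collapse = ", "))
  retained <- character(0)
  report <- data.frame(dropped = character(0), blockedBy = character(0),
                       r = numeric(0), stringsAsFactors = FALSE)
  for (v in priority) {
    r <- vapply(retained, function(u) {
      if (sds[v] == 0 || sds[u] == 0) return(0)
      stats::cor(V[, v], V[, u])
    }, numeric(1))
    if (length(r) == 0L || all(abs(r) <= rThreshold)) {
      retained <- c(retained, v)
    } else {
      blk <- retained[which.max(abs(r))]
      report <- rbind(report, data.frame(dropped = v, blockedBy = blk,
                                         r = r[[which.max(abs(r))]],
                                         stringsAsFactors = FALSE))
    }
  }
  list(stack = stack[retained], report = report)
}
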