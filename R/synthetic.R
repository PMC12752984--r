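# Synthetic landscape generator: spatially autocorrelated indicator fields,
# categorical patch maps, Euclidean distance / buffer-ring derivation of
# locational indicators, and overlay evaluation units. Everything is
# deterministic for a fixed seed so the whole pipeline is testable without
# any external data.

#' Generate a spatially autocorrelated continuous field
#'
#' Draws white noise on the grid, smooths it with a Gaussian kernel of
#' scale \code{corrLength} (truncated at 4 sigma), and affinely rescales
#' the result so that its minimum and maximum equal \code{lo} and
#' \code{hi} exactly. With \code{corrLength = 0} the field is rescaled
#' white noise. A constant field (e.g. on a 1 x 1 grid) is set to the
#' interval midpoint, since no affine map can realise both bounds there.
#'
#' @param grid a [GridSpec-class].
#' @param lo,hi target minimum and maximum (\code{lo < hi}).
#' @param corrLength correlation length in metres (>= 0); the Gaussian
#'   smoothing sigma is \code{corrLength / cellSize} cells.
#' @param seed integer seed; identical calls return identical layers.
#' @param indicatorId id for the returned layer.
#' @return An [IndicatorLayer-class].
#' @examples
#' f <- generateField(gridSpec(50, 50), lo = 0, hi = 28.0476,
#'                    corrLength = 300, seed = 1)
#' range(layerValues(f))
#' @export
generateField <- function(grid, lo, hi, corrLength = 300, seed = 1,
                          indicatorId = "I") {
  stopifnot(is(grid, "GridSpec"))
  if (!isTRUE(lo < hi)) stop("lo must be < hi")
  if (!isTRUE(corrLength >= 0)) stop("corrLength must be >= 0")
  vals <- withSeed(seed, {
    x <- matrix(stats::rnorm(grid@nrows * grid@ncols),
                grid@nrows, grid@ncols)
    gaussSmooth(x, corrLength / grid@cellSize)
  })
  indicatorLayer(grid, rescaleTo(vals, lo, hi), indicatorId)
}

#' Generate a categorical patch map
#'
#' Scatters seed points at a density of roughly one per
#' \code{patchScale^2} of grid area, assigns each seed a class drawn from
#' the legend, and labels every cell with the class of its nearest seed
#' (a Voronoi tessellation), producing contiguous patches. Every emitted
#' class id is a member of the legend; small grids may not exhibit all
#' classes.
#'
#' @param grid a [GridSpec-class].
#' @param legend character vector of category names (class ids are
#'   1..length(legend)), or an already-named character vector.
#' @param patchScale characteristic patch diameter in metres.
#' @param seed integer seed.
#' @param indicatorId id for the returned layer.
#' @return A [CategoricalLayer-class].
#' @export
generateCategorical <- function(grid, legend, patchScale = 600, seed = 1,
                                indicatorId = "C") {
  stopifnot(is(grid, "GridSpec"))
  if (length(legend) < 1L) stop("legend must be non-empty")
  if (is.null(names(legend))) names(legend) <- as.character(seq_along(legend))
  nr <- grid@nrows; nc <- grid@ncols
  ncell <- nr * nc
  ids <- as.integer(names(legend))
  cls <- withSeed(seed, {
    areaM2 <- ncell * grid@cellSize^2
    k <- max(1L, min(ncell, as.integer(round(areaM2 / patchScale^2))))
    seedCells <- sample.int(ncell, k)
    seedClass <- ids[sample.int(length(ids), k, replace = TRUE)]
    sr <- (seedCells - 1L) %% nr + 1L
    sc <- (seedCells - 1L) %/% nr + 1L
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    best <- matrix(Inf, nr, nc)
    out <- matrix(seedClass[1L], nr, nc)
    for (i in seq_len(k)) {
      d2 <- (rows - sr[i])^2 + (cols - sc[i])^2
      upd <- d2 < best
      best[upd] <- d2[upd]
      out[upd] <- seedClass[i]
    }
    out
  })
  categoricalLayer(grid, cls, legend, indicatorId)
}

#' Exact Euclidean distance transform
#'
#' Per-cell Euclidean distance in metres (centre to centre) to the
#' nearest cell of \code{targetClass}; 0 on target cells. Uses the exact
#' two-pass lower-envelope-of-parabolas algorithm, so the result equals
#' the brute-force minimum over all target cells.
#'
#' @param mask a [CategoricalLayer-class].
#' @param targetClass integer class id; must occur at least once.
#' @param indicatorId id for the returned layer.
#' @return An [IndicatorLayer-class] of distances in metres.
#' @export
distanceTransform <- function(mask, targetClass, indicatorId = "dist") {
  stopifnot(is(mask, "CategoricalLayer"))
  tgt <- !is.na(mask@classIds) & mask@classIds == as.integer(targetClass)
  if (!any(tgt))
    stop(sprintf("target class %s does not occur in the mask", targetClass))
  d2 <- edt2(tgt)
  indicatorLayer(mask@grid, sqrt(d2) * mask@grid@cellSize, indicatorId)
}

# squared distance (in cells) to nearest TRUE cell
BIG <- 1e12
edt2 <- function(target) {
  nr <- nrow(target); nc <- ncol(target)
  # pass 1: per column, squared distance to nearest target within the column
  g <- matrix(BIG, nr, nc)
  for (j in seq_len(nc)) {
    col <- target[, j]
    if (!any(col)) next
    d <- rep(BIG, nr)
    cur <- BIG
    for (i in seq_len(nr)) {            # downward sweep
      cur <- if (col[i]) 0 else cur + 1
      d[i] <- cur
    }
    cur <- BIG
    for (i in rev(seq_len(nr))) {       # upward sweep
      cur <- if (col[i]) 0 else cur + 1
      d[i] <- min(d[i], cur)
    }
    g[, j] <- pmin(d^2, BIG)
  }
  # pass 2: per row, lower envelope of parabolas over column offsets
  out <- matrix(BIG, nr, nc)
  for (i in seq_len(nr)) out[i, ] <- edt1(g[i, ])
  out
}

edt1 <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      if (k > 1L && s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Classify distances into buffer rings
#'
#' Assigns ring \code{k} (1-based) to distances in
#' \code{[(k-1) w, k w)}; all distances at or beyond \code{(n-1) w}
#' collapse into the outermost ring \code{n}.
#'
#' @param distance an [IndicatorLayer-class] of non-negative distances
#'   (metres), e.g. from [distanceTransform()].
#' @param ringWidth buffer interval width in metres (default 500).
#' @param nRings number of rings (default 5).
#' @param legendNames optional ring names; defaults to the five-level
#'   proximity vocabulary (Closer .. Farther) when \code{nRings == 5},
#'   otherwise \code{"ring k"}.
#' @param indicatorId id for the returned layer.
#' @return A [CategoricalLayer-class] of ring ids 1..nRings.
#' @export
ringClassify <- function(distance, ringWidth = 500, nRings = 5,
                         legendNames = NULL, indicatorId = "rings") {
  stopifnot(is(distance, "IndicatorLayer"))
  d <- distance@values
  if (any(d < 0, na.rm = TRUE)) stop("distances must be >= 0")
  if (is.null(legendNames)) {
    legendNames <- if (nRings == 5)
      c("Closer", "Close", "Moderate", "Far", "Farther")
    else paste("ring", seq_len(nRings))
  }
  stopifnot(length(legendNames) == nRings)
  ring <- pmin(floor(d / ringWidth) + 1, nRings)
  mode(ring) <- "integer"
  legend <- stats::setNames(legendNames, as.character(seq_len(nRings)))
  categoricalLayer(distance@grid, ring, legend, indicatorId)
}

#' Build evaluation units by layer overlay
#'
#' Overlays the land-use, soil and administrative layers and forms one
#' evaluation unit per 4-connected component of cells sharing an
#' identical (landuse, soil, admin) triple, restricted to farmland
#' cells. Components smaller than \code{minAreaHm2} (slivers from the
#' overlay) are merged into their largest adjacent unit, smallest sliver
#' first; an isolated sliver with no neighbour is kept.
#'
#' @param landuse,soil,admin [CategoricalLayer-class] objects on one grid.
#' @param minAreaHm2 minimum unit area in hm2 (default 0.36, i.e. four
#'   30 m cells).
#' @param farmlandClasses integer land-use class ids counted as farmland;
#'   default: the class(es) whose legend name is \code{"farmland"}
#'   (case-insensitive), or every class if none is so named.
#' @return A [UnitMap-class].
#' @export
buildEvaluationUnits <- function(landuse, soil, admin, minAreaHm2 = 0.36,
                                 farmlandClasses = NULL) {
  stopIfGridMismatch(landuse, soil, "landuse and soil layers")
  stopIfGridMismatch(landuse, admin, "landuse and admin layers")
  grid <- landuse@grid
  if (is.null(farmlandClasses)) {
    hit <- grep("^farmland$", landuse@legend, ignore.case = TRUE)
    farmlandClasses <- if (length(hit))
      as.integer(names(landuse@legend)[hit])
    else as.integer(names(landuse@legend))
  }
  lu <- landuse@classIds; so <- soil@classIds; ad <- admin@classIds
  farm <- !is.na(lu) & lu %in% farmlandClasses & !is.na(so) & !is.na(ad)
  labels <- labelComponents(lu, so, ad, farm)
  labels <- mergeSlivers(labels, minAreaHm2 / cellAreaHa(grid))
  # relabel compactly in row-major (raster) order of first appearance
  seen <- unique(t(labels)[t(labels) != 0L])
  relab <- integer(max(labels, 1L))
  relab[seen] <- seq_along(seen)
  labels[labels != 0L] <- relab[labels[labels != 0L]]
  ids <- seq_along(seen)
  cellAreaHm2 <- cellAreaHa(grid)
  units <- do.call(rbind, lapply(ids, function(id) {
    cells <- which(labels == id)
    data.frame(unit_id = id,
               region_id = ad[cells[1L]],
               soil_id = so[cells[1L]],
               landuse_id = lu[cells[1L]],
               n_cells = length(cells),
               area_hm2 = length(cells) * cellAreaHm2)
  }))
  if (is.null(units))
    units <- data.frame(unit_id = integer(), region_id = integer(),
                        soil_id = integer(), landuse_id = integer(),
                        n_cells = integer(), area_hm2 = numeric())
  new("UnitMap", grid = grid, labels = labels, units = units)
}

# 4-connected components of identical (landuse, soil, admin) triples over
# the farmland mask; union-find with path halving.
labelComponents <- function(lu, so, ad, farm) {
  nr <- nrow(lu); nc <- ncol(lu)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  nlab <- 0L
  findRoot <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  same <- function(i1, j1, i2, j2) {
    lu[i1, j1] == lu[i2, j2] && so[i1, j1] == so[i2, j2] &&
      ad[i1, j1] == ad[i2, j2]
  }
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!farm[i, j]) next
    up   <- i > 1L && farm[i - 1L, j] && same(i, j, i - 1L, j)
    left <- j > 1L && farm[i, j - 1L] && same(i, j, i, j - 1L)
    if (up && left) {
      ru <- findRoot(lab[i - 1L, j]); rl <- findRoot(lab[i, j - 1L])
      parent[max(ru, rl)] <- min(ru, rl)
      lab[i, j] <- min(ru, rl)
    } else if (up) {
      lab[i, j] <- lab[i - 1L, j]
    } else if (left) {
      lab[i, j] <- lab[i, j - 1L]
    } else {
      nlab <- nlab + 1L
      parent[nlab] <- nlab
      lab[i, j] <- nlab
    }
  }
  idx <- lab != 0L
  if (any(idx)) lab[idx] <- vapply(lab[idx], findRoot, integer(1))
  lab
}

# Merge components smaller than minCells into their largest 4-adjacent
# neighbour, smallest component first (ties: lowest label). Isolated
# slivers without neighbours are kept.
mergeSlivers <- function(lab, minCells) {
  repeat {
    sizes <- table(lab[lab != 0L])
    small <- as.integer(names(sizes)[sizes < minCells])
    if (!length(small)) return(lab)
    merged <- FALSE
    ord <- small[order(sizes[as.character(small)], small)]
    for (s in ord) {
      nb <- neighbourLabels(lab, s)
      if (!length(nb)) next
      nbSizes <- sizes[as.character(nb)]
      target <- nb[order(-as.numeric(nbSizes), nb)][1L]
      lab[lab == s] <- target
      merged <- TRUE
      break  # recompute sizes after each merge
    }
    if (!merged) return(lab)
  }
}

neighbourLabels <- function(lab, s) {
  cells <- which(lab == s, arr.ind = TRUE)
  nr <- nrow(lab); nc <- ncol(lab)
  out <- integer(0)
  for (k in seq_len(nrow(cells))) {
    i <- cells[k, 1L]; j <- cells[k, 2L]
    if (i > 1L) out <- c(out, lab[i - 1L, j])
    if (i < nr) out <- c(out, lab[i + 1L, j])
    if (j > 1L) out <- c(out, lab[i, j - 1L])
    if (j < nc) out <- c(out, lab[i, j + 1L])
  }
  setdiff(unique(out), c(0L, s))
}
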