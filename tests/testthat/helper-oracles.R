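# Independent oracles used across the suite. These deliberately use naive
# algorithms (brute force, flood fill, exhaustive enumeration) so they
# share no code with the implementations they check.

# minimum Euclidean distance from every cell to any TRUE cell, in cells
bruteForceEDT <- function(target) {
  idx <- which(target, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(target), ncol(target))
  for (i in seq_len(nrow(target))) for (j in seq_len(ncol(target)))
    out[i, j] <- sqrt(min((idx[, 1] - i)^2 + (idx[, 2] - j)^2))
  out
}

# recursive flood fill (4-connectivity) counting components of identical
# (landuse, soil, admin) triples over a mask
floodFillComponents <- function(lu, so, ad, farm) {
  nr <- nrow(lu); nc <- ncol(lu)
  seen <- matrix(FALSE, nr, nc)
  ncomp <- 0L
  for (si in seq_len(nr)) for (sj in seq_len(nc)) {
    if (!farm[si, sj] || seen[si, sj]) next
    ncomp <- ncomp + 1L
    stack <- list(c(si, sj))
    seen[si, sj] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- p[1]; j <- p[2]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        if (seen[ii, jj] || !farm[ii, jj]) next
        if (lu[ii, jj] == lu[i, j] && so[ii, jj] == so[i, j] &&
            ad[ii, jj] == ad[i, j]) {
          seen[ii, jj] <- TRUE
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  ncomp
}

# exhaustive search over all placements of k-1 breaks in sorted values;
# returns the minimal total within-class sum of squared deviations
bruteForceJenksSSD <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(ssd(x))
  best <- Inf
  for (cut in utils::combn(n - 1, k - 1, simplify = FALSE)) {
    bounds <- c(0, cut, n)
    tot <- 0
    for (c2 in seq_len(k))
      tot <- tot + ssd(x[(bounds[c2] + 1):bounds[c2 + 1]])
    if (tot < best) best <- tot
  }
  best
}

# per-unit mean by explicit looping over the label matrix
naiveZonalMean <- function(values, labels, ids) {
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (id in ids) {
    v <- values[labels == id]
    v <- v[!is.na(v)]
    if (length(v)) out[as.character(id)] <- mean(v)
  }
  out
}

# small all-constant categorical layer
constantCat <- function(grid, legend, classId = 1L, indicatorId = "C") {
  categoricalLayer(grid, matrix(classId, grid@nrows, grid@ncols),
                   legend, indicatorId)
}
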