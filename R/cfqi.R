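# Comprehensive farmland quality index: zonal aggregation of membership
# scores per evaluation unit, weighted summation into the quality index,
# exact Jenks natural-breaks grading, and grade-area tabulation.

#' Zonal mean of a layer over evaluation units
#'
#' Arithmetic mean of the non-nodata cell values of a layer within each
#' evaluation unit. A unit with no valid cells gets NA and a warning
#' (flagged, never silently zero).
#'
#' @param layer an [IndicatorLayer-class] (typically a
#'   [ScoreLayer-class]) on the same grid as \code{units}.
#' @param units a [UnitMap-class].
#' @return Named numeric vector of per-unit means, names = unit ids.
#' @export
zonalMean <- function(layer, units) {
  stopifnot(is(layer, "IndicatorLayer"), is(units, "UnitMap"))
  stopIfGridMismatch(layer, units, "layer and unit map")
  ids <- units@units$unit_id
  lab <- units@labels
  v <- layer@values
  keep <- lab != 0L & !is.na(lab) & !is.na(v)
  sums <- rowsum(v[keep], lab[keep])
  cnts <- rowsum(rep(1, sum(keep)), lab[keep])
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  out[rownames(sums)] <- sums[, 1L] / cnts[, 1L]
  if (anyNA(out))
    warning(sprintf("%d unit(s) have no valid cells in layer '%s'",
                    sum(is.na(out)), layer@indicatorId))
  out
}

#' Comprehensive farmland quality index per unit
#'
#' Weighted sum of per-unit membership scores:
#' \eqn{IFI = \sum_i C_i F_i}, with \eqn{C_i} the indicator weights and
#' \eqn{F_i} the unit's mean membership scores. With weights summing to
#' w and scores in [0, 1], IFI lies in [0, w].
#'
#' @param unitScores numeric matrix (or data.frame) of per-unit scores,
#'   rows = units (rownames = unit ids), columns = indicator ids.
#' @param weights named numeric weight vector; every weight name must
#'   have a score column.
#' @return Named numeric vector of IFI values per unit.
#' @examples
#' sc <- matrix(c(1, 0, 0.5, 0.5), 2, 2,
#'              dimnames = list(c("1", "2"), c("A", "B")))
#' computeIFI(sc, c(A = 0.5, B = 0.5))
#' @export
computeIFI <- function(unitScores, weights) {
  unitScores <- as.matrix(unitScores)
  missing <- setdiff(names(weights), colnames(unitScores))
  if (length(missing))
    stop(sprintf("missing indicator score(s): %s",
                 paste(missing, collapse = ", ")))
  m <- unitScores[, names(weights), drop = FALSE]
  if (anyNA(m))
    stop("NA unit scores: every weighted indicator needs a score per unit")
  ifi <- as.vector(m %*% weights)
  stats::setNames(ifi, rownames(unitScores))
}

# Exact Fisher-Jenks dynamic programme on (sorted unique value, weight)
# pairs; returns 1-based start index of each class (ascending).
fisherJenks <- function(x, w, k) {
  n <- length(x)
  cw <- cumsum(w)
  cwx <- cumsum(w * x)
  cwx2 <- cumsum(w * x^2)
  # weighted SSD of x[i..j]
  ssd <- function(i, j) {
    W <- cw[j] - if (i > 1L) cw[i - 1L] else 0
    S <- cwx[j] - if (i > 1L) cwx[i - 1L] else 0
    Q <- cwx2[j] - if (i > 1L) cwx2[i - 1L] else 0
    Q - S^2 / W
  }
  cost <- matrix(Inf, n, n)        # cost[i, j] for i <= j
  for (j in seq_len(n)) {
    W <- cw[j] - c(0, cw[seq_len(j - 1L)])
    S <- cwx[j] - c(0, cwx[seq_len(j - 1L)])
    Q <- cwx2[j] - c(0, cwx2[seq_len(j - 1L)])
    cost[seq_len(j), j] <- Q - S^2 / W
  }
  D <- matrix(Inf, k, n)           # D[m, j]: best cost of x[1..j] in m classes
  B <- matrix(1L, k, n)            # start index of the last class
  D[1L, ] <- cost[1L, ]
  if (k > 1L) for (m in 2:k) {
    for (j in m:n) {
      cand <- D[m - 1L, (m - 1L):(j - 1L)] + cost[m:j, j]
      best <- which.min(cand)
      D[m, j] <- cand[best]
      B[m, j] <- (m:j)[best]
    }
  }
  starts <- integer(k)
  j <- n
  for (m in k:1) {
    starts[m] <- B[m, j]
    j <- starts[m] - 1L
  }
  list(starts = starts, totalSSD = D[k, n])
}

#' Jenks natural-breaks classification
#'
#' Exact Fisher dynamic programme minimising the total within-class sum
#' of squared deviations, run on the sorted distinct values with
#' frequency weights (duplicate compression), so the result is exact and
#' deterministic for any input order. The partition is returned as a
#' [GradeScheme-class] whose grade I holds the highest class; interval
#' boundaries are placed at the minimum observed value of the upper
#' class, so classification with the default half-open convention
#' reproduces the optimal partition exactly.
#'
#' @param values numeric vector (length >= k, with >= k distinct values).
#' @param k number of classes (default 5).
#' @param labels grade labels, best first.
#' @return A [GradeScheme-class]; the attribute \code{"withinSSD"}
#'   carries the optimal total within-class sum of squared deviations.
#' @examples
#' jenksBreaks(c(1, 2, 3, 100, 101, 102), k = 2)
#' @export
jenksBreaks <- function(values, k = 5,
                        labels = as.character(utils::as.roman(seq_len(k)))) {
  values <- values[!is.na(values)]
  ux <- sort(unique(values))
  if (length(ux) < k)
    stop(sprintf("need at least %d distinct values, got %d", k, length(ux)))
  w <- as.numeric(table(factor(values, levels = ux)))
  fit <- fisherJenks(ux, w, k)
  starts <- fit$starts               # ascending class start indices
  # ascending class c spans ux[starts[c] .. ends[c]]
  ends <- c(starts[-1L] - 1L, length(ux))
  loAsc <- ux[starts]
  # descending grades: grade 1 = highest class
  ord <- k:1
  lower <- loAsc[ord]
  upper <- c(ux[length(ux)], loAsc[ord][-k])
  sch <- gradeScheme(lower = lower, upper = upper, labels = labels)
  attr(sch, "withinSSD") <- fit$totalSSD
  sch
}

#' Classify quality-index values into grades
#'
#' Interval membership against a [GradeScheme-class]: each grade's
#' interval is half-open on its lower bound, \code{[lo, hi)}, except the
#' top interval which includes its maximum. Values outside all intervals
#' are flagged as ungraded (NA, with a warning). Higher index values
#' never map to a worse grade.
#'
#' @param ifi numeric vector of quality-index values (names kept).
#' @param scheme a [GradeScheme-class].
#' @return Factor of grade labels (levels = scheme labels, best first),
#'   NA for ungraded values.
#' @export
classifyGrades <- function(ifi, scheme) {
  stopifnot(is(scheme, "GradeScheme"))
  k <- length(scheme@labels)
  g <- rep(NA_integer_, length(ifi))
  for (i in seq_len(k)) {
    topIncl <- i == 1L
    sel <- !is.na(ifi) & ifi >= scheme@lower[i] &
      (ifi < scheme@upper[i] | (topIncl & ifi <= scheme@upper[i]))
    g[sel] <- i
  }
  if (any(is.na(g) & !is.na(ifi)))
    warning(sprintf("%d value(s) fall outside all grade intervals (ungraded)",
                    sum(is.na(g) & !is.na(ifi))))
  out <- factor(scheme@labels[g], levels = scheme@labels)
  names(out) <- names(ifi)
  out
}

#' Tabulate grade areas by region
#'
#' Cross-tabulates evaluation-unit areas by administrative region and
#' quality grade. Every unit must be graded; ungraded units raise an
#' error. Marginals are exact sums of the cell-count areas, so row sums
#' equal region totals and column sums equal grade totals by
#' construction.
#'
#' @param grades factor of per-unit grades, aligned with (or named by)
#'   the rows of the unit table.
#' @param units a [UnitMap-class].
#' @param regionNames optional named character vector mapping region ids
#'   to display names (e.g. an admin-layer legend).
#' @return Numeric matrix of areas in hm2, regions x grades, with all
#'   scheme grades as columns.
#' @export
tabulateAreas <- function(grades, units, regionNames = NULL) {
  stopifnot(is(units, "UnitMap"))
  tab <- units@units
  if (!is.null(names(grades))) grades <- grades[as.character(tab$unit_id)]
  if (length(grades) != nrow(tab))
    stop("grades must align with the unit table")
  if (anyNA(grades))
    stop(sprintf("%d ungraded unit(s); every unit must be graded",
                 sum(is.na(grades))))
  region <- factor(tab$region_id, levels = sort(unique(tab$region_id)))
  m <- tapply(tab$area_hm2, list(region, grades), sum, default = 0)
  m <- as.matrix(m)
  if (!is.null(regionNames)) {
    hit <- match(rownames(m), names(regionNames))
    rownames(m)[!is.na(hit)] <- regionNames[hit[!is.na(hit)]]
  }
  m
}
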