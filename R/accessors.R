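# Constructors, accessors and show() methods for the core classes.

#' Construct a grid specification
#'
#' @param nrows,ncols grid dimensions.
#' @param cellSize cell edge length in metres (default 30).
#' @param originX,originY projected coordinates of the top-left corner.
#' @param crsTag free-text CRS label.
#' @return A [GridSpec-class].
#' @examples
#' g <- gridSpec(50, 50)
#' cellAreaHa(g)  # 0.09 hm2 for a 30 m cell
#' @export
gridSpec <- function(nrows, ncols, cellSize = 30,
                     originX = 0, originY = 0, crsTag = "local-metric") {
  new("GridSpec", nrows = as.integer(nrows), ncols = as.integer(ncols),
      cellSize = as.numeric(cellSize), originX = as.numeric(originX),
      originY = as.numeric(originY), crsTag = as.character(crsTag))
}

#' Construct a continuous indicator layer
#'
#' @param grid a [GridSpec-class].
#' @param values numeric matrix matching the grid; NA = nodata.
#' @param indicatorId indicator id string.
#' @return An [IndicatorLayer-class].
#' @export
indicatorLayer <- function(grid, values, indicatorId = "I") {
  if (is.null(dim(values)) && length(values) == grid@nrows * grid@ncols)
    dim(values) <- c(grid@nrows, grid@ncols)
  storage.mode(values) <- "double"
  new("IndicatorLayer", grid = grid, indicatorId = indicatorId,
      values = values)
}

#' Construct a categorical layer
#'
#' @param grid a [GridSpec-class].
#' @param classIds integer matrix of class ids matching the grid.
#' @param legend named character vector mapping class ids to names.
#' @param indicatorId indicator id string.
#' @return A [CategoricalLayer-class].
#' @export
categoricalLayer <- function(grid, classIds, legend, indicatorId = "C") {
  storage.mode(classIds) <- "integer"
  new("CategoricalLayer", grid = grid, indicatorId = indicatorId,
      classIds = classIds, legend = legend)
}

#' Construct a membership specification
#'
#' @param indicatorId indicator id.
#' @param kind \code{"decreasing"}, \code{"peak"} or \code{"linear"}.
#' @param a,b,c function coefficients; see [MembershipSpec-class].
#' @param uLo,uHi indicator domain bounds.
#' @return A [MembershipSpec-class].
#' @examples
#' slope <- membershipSpec("I2", "decreasing", a = 0.0157, c = 0,
#'                         uLo = 0, uHi = 28.0476)
#' evaluateMembership(slope, 10)
#' @export
membershipSpec <- function(indicatorId, kind, a, b = NA_real_, c = NA_real_,
                           uLo, uHi) {
  new("MembershipSpec", indicatorId = indicatorId, kind = kind,
      a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
      uLo = as.numeric(uLo), uHi = as.numeric(uHi))
}

#' Construct a conceptual scoring scale
#'
#' @param indicatorId indicator id.
#' @param categories category names, best first.
#' @param scores strictly decreasing scores in (0, 1].
#' @return A [ConceptualScale-class].
#' @export
conceptualScale <- function(indicatorId, categories, scores) {
  new("ConceptualScale", indicatorId = indicatorId,
      categories = as.character(categories), scores = as.numeric(scores))
}

#' Construct a grade scheme from interval bounds
#'
#' @param lower,upper per-grade interval bounds, grade I first
#'   (\code{upper} decreasing, intervals contiguous).
#' @param labels grade labels; default Roman numerals.
#' @return A [GradeScheme-class].
#' @examples
#' sch <- gradeScheme(lower = c(0.6, 0.4), upper = c(0.8, 0.6))
#' classifyGrades(c(0.7, 0.5), sch)
#' @export
gradeScheme <- function(lower, upper, labels = as.character(utils::as.roman(seq_along(lower)))) {
  new("GradeScheme", labels = labels,
      lower = as.numeric(lower), upper = as.numeric(upper))
}

#' Construct economic parameters
#'
#' @param price market price, yuan/t.
#' @param cost production cost, yuan/t.
#' @param discountRate optional single-year discount rate in [0, 1).
#' @param seasonal optional 2-column matrix or data.frame of per-season
#'   \code{(price, cost)} pairs (one row per cropping season); when given,
#'   \code{price} and \code{cost} are taken as the arithmetic means across
#'   seasons and the scalar arguments are ignored.
#' @return An [EconomicParams-class].
#' @examples
#' economicParams(price = 2640, cost = 1760)
#' economicParams(seasonal = data.frame(price = c(2600, 2680),
#'                                      cost  = c(1700, 1820)))
#' @export
economicParams <- function(price = 0, cost = 0, discountRate = NA_real_,
                           seasonal = NULL) {
  if (!is.null(seasonal)) {
    seasonal <- as.data.frame(seasonal)
    if (!all(c("price", "cost") %in% names(seasonal)))
      stop("seasonal must have columns 'price' and 'cost'")
    price <- mean(seasonal$price)
    cost <- mean(seasonal$cost)
  }
  new("EconomicParams", price = as.numeric(price), cost = as.numeric(cost),
      discountRate = as.numeric(discountRate))
}

## ---- accessors ----

#' Grid accessors
#'
#' @param x an object carrying a grid (layer, unit map) or a
#'   [GridSpec-class] itself.
#' @return \code{gridOf()} the [GridSpec-class]; \code{cellAreaHa()} the
#'   area of one cell in hm2; \code{layerValues()} the value matrix of a
#'   layer (class ids for categorical layers); \code{classLegend()} the
#'   legend of a categorical layer; \code{unitTable()} the unit
#'   data.frame and \code{unitLabels()} the label matrix of a
#'   [UnitMap-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridOf", function(x) standardGeneric("gridOf"))
#' @rdname accessors
setMethod("gridOf", "GridSpec", function(x) x)
#' @rdname accessors
setMethod("gridOf", "IndicatorLayer", function(x) x@grid)
#' @rdname accessors
setMethod("gridOf", "CategoricalLayer", function(x) x@grid)
#' @rdname accessors
setMethod("gridOf", "UnitMap", function(x) x@grid)

#' @rdname accessors
#' @export
cellAreaHa <- function(x) {
  g <- gridOf(x)
  g@cellSize^2 / 1e4
}

#' @rdname accessors
#' @export
setGeneric("layerValues", function(x) standardGeneric("layerValues"))
#' @rdname accessors
setMethod("layerValues", "IndicatorLayer", function(x) x@values)
#' @rdname accessors
setMethod("layerValues", "CategoricalLayer", function(x) x@classIds)

#' @rdname accessors
#' @export
classLegend <- function(x) {
  stopifnot(is(x, "CategoricalLayer"))
  x@legend
}

#' @rdname accessors
#' @export
unitTable <- function(x) {
  stopifnot(is(x, "UnitMap"))
  x@units
}

#' @rdname accessors
#' @export
unitLabels <- function(x) {
  stopifnot(is(x, "UnitMap"))
  x@labels
}

#' Grade-scheme accessors
#'
#' @param x a [GradeScheme-class].
#' @return \code{gradeLabels()} the grade labels; \code{gradeBounds()} a
#'   data.frame with columns \code{grade}, \code{lower}, \code{upper}.
#' @export
gradeLabels <- function(x) {
  stopifnot(is(x, "GradeScheme"))
  x@labels
}

#' @rdname gradeLabels
#' @export
gradeBounds <- function(x) {
  stopifnot(is(x, "GradeScheme"))
  data.frame(grade = x@labels, lower = x@lower, upper = x@upper)
}

sameGrid <- function(a, b) {
  ga <- gridOf(a); gb <- gridOf(b)
  identical(ga@nrows, gb@nrows) && identical(ga@ncols, gb@ncols) &&
    isTRUE(all.equal(ga@cellSize, gb@cellSize)) &&
    identical(ga@crsTag, gb@crsTag)
}

stopIfGridMismatch <- function(a, b, what = "layers") {
  if (!sameGrid(a, b))
    stop(sprintf("grid mismatch: %s must share one GridSpec", what))
  invisible(TRUE)
}

## ---- show methods ----

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells, %g m resolution (%g hm2/cell), crs '%s'\n",
              object@nrows, object@ncols, object@cellSize,
              cellAreaHa(object), object@crsTag))
})

setMethod("show", "IndicatorLayer", function(object) {
  v <- object@values
  cat(sprintf("IndicatorLayer '%s': %d x %d, range [%g, %g], %d nodata\n",
              object@indicatorId, nrow(v), ncol(v),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
})

setMethod("show", "CategoricalLayer", function(object) {
  cat(sprintf("CategoricalLayer '%s': %d x %d, %d classes (%s)\n",
              object@indicatorId, nrow(object@classIds), ncol(object@classIds),
              length(object@legend),
              paste(utils::head(object@legend, 3), collapse = ", ")))
})

setMethod("show", "UnitMap", function(object) {
  cat(sprintf("UnitMap: %d evaluation units over %d farmland cells, total %.2f hm2 (mean %.2f hm2)\n",
              nrow(object@units), sum(object@units$n_cells),
              sum(object@units$area_hm2), mean(object@units$area_hm2)))
})

setMethod("show", "MembershipSpec", function(object) {
  cat(sprintf("MembershipSpec '%s' (%s): a=%g b=%g c=%g on [%g, %g]\n",
              object@indicatorId, object@kind, object@a, object@b, object@c,
              object@uLo, object@uHi))
})

setMethod("show", "ConceptualScale", function(object) {
  cat(sprintf("ConceptualScale '%s': %d categories, scores %s\n",
              object@indicatorId, length(object@categories),
              paste(format(object@scores), collapse = " > ")))
})

setMethod("show", "GradeScheme", function(object) {
  cat("GradeScheme:\n")
  b <- gradeBounds(object)
  for (i in seq_len(nrow(b)))
    cat(sprintf("  %-4s [%.4f, %.4f%s\n", b$grade[i], b$lower[i], b$upper[i],
                if (i == 1L) "]" else ")"))
})

setMethod("show", "EconomicParams", function(object) {
  cat(sprintf("EconomicParams: price %g yuan/t, cost %g yuan/t, margin %g yuan/t%s\n",
              object@price, object@cost, object@price - object@cost,
              if (is.na(object@discountRate)) ""
              else sprintf(", discount rate %g", object@discountRate)))
})

setMethod("show", "ValuationReport", function(object) {
  cat("ValuationReport\n")
  tab <- data.frame(grade = names(object@unitValues),
                    area_hm2 = round(object@gradeAreas, 2),
                    unit_value_yuan_hm2 = round(object@unitValues, 2),
                    total_yuan = round(object@gradeTotals, 2),
                    value_share_pct = round(object@valueShares, 2))
  print(tab, row.names = FALSE)
  cat(sprintf("Grand total: %.2f yuan\n", object@grandTotal))
  if (!is.na(object@presentValue))
    cat(sprintf("Present value (r = %g): %.2f yuan\n",
                object@params@discountRate, object@presentValue))
})
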