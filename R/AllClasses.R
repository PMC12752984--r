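#' @import methods
NULL

#' Grid geometry of a raster layer
#'
#' Describes a regular, projected, row-major grid: the number of rows and
#' columns, the square cell size in metres, the coordinate of the top-left
#' corner, and a free-text CRS tag. All layers taking part in one analysis
#' must share an identical \code{GridSpec}; the package validates this and
#' refuses to combine mismatched grids.
#'
#' The area of one cell is \code{cellSize^2 / 10000} hectares (hm2), so a
#' 30 m cell covers 0.09 hm2. Areas are always cell counts times cell area;
#' no geodesic correction is applied.
#'
#' @slot nrows,ncols integer, grid dimensions (both >= 1).
#' @slot cellSize numeric, cell edge length in metres (> 0); default 30.
#' @slot originX,originY numeric, projected coordinates (metres) of the
#'   top-left corner of the top-left cell.
#' @slot crsTag character, label for the projected CRS (not interpreted).
#'
#' @seealso [gridSpec()] for the user constructor, [cellAreaHa()].
#' @export
setClass("GridSpec",
  representation(
    nrows = "integer", ncols = "integer",
    cellSize = "numeric", originX = "numeric", originY = "numeric",
    crsTag = "character"
  ),
  prototype(
    nrows = 1L, ncols = 1L, cellSize = 30, originX = 0, originY = 0,
    crsTag = "local-metric"
  )
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@nrows) != 1L || is.na(object@nrows) || object@nrows < 1L)
    msg <- c(msg, "nrows must be a single integer >= 1")
  if (length(object@ncols) != 1L || is.na(object@ncols) || object@ncols < 1L)
    msg <- c(msg, "ncols must be a single integer >= 1")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number (metres)")
  if (length(msg)) msg else TRUE
})

#' Continuous indicator raster
#'
#' One gridded continuous indicator (slope, soil pH, ...) on a common grid.
#' Values are stored as a numeric matrix in row-major raster orientation
#' (matrix row 1 = northernmost row); \code{NA} marks nodata cells.
#'
#' @slot grid a [GridSpec-class].
#' @slot indicatorId character id, e.g. \code{"I2"} for slope or \code{"T"}
#'   for annual mean temperature.
#' @slot values numeric matrix, \code{nrows x ncols}; \code{NA} = nodata.
#'
#' @seealso [indicatorLayer()], [generateField()], [scoreLayer()].
#' @export
setClass("IndicatorLayer",
  representation(grid = "GridSpec", indicatorId = "character",
                 values = "matrix")
)

setValidity("IndicatorLayer", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (!identical(d, c(object@grid@nrows, object@grid@ncols)))
    msg <- c(msg, sprintf("values must be a %d x %d matrix",
                          object@grid@nrows, object@grid@ncols))
  if (!is.numeric(object@values))
    msg <- c(msg, "values must be numeric")
  else if (any(is.infinite(object@values)))
    msg <- c(msg, "values must be finite where not NA")
  if (length(object@indicatorId) != 1L)
    msg <- c(msg, "indicatorId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Categorical raster with a legend
#'
#' A gridded categorical layer (land use, soil type, administrative region,
#' conceptual indicator classes). Cell values are integer class ids;
#' \code{NA} marks nodata. The legend maps every class id to a category
#' name, and every id present in the raster must appear in the legend.
#'
#' @slot grid a [GridSpec-class].
#' @slot indicatorId character id (e.g. \code{"I1"}, \code{"landuse"}).
#' @slot classIds integer matrix of class ids; \code{NA} = nodata.
#' @slot legend named character vector: names are class ids (as strings),
#'   values are category names.
#'
#' @seealso [categoricalLayer()], [generateCategorical()], [ringClassify()].
#' @export
setClass("CategoricalLayer",
  representation(grid = "GridSpec", indicatorId = "character",
                 classIds = "matrix", legend = "character")
)

setValidity("CategoricalLayer", function(object) {
  msg <- character()
  d <- dim(object@classIds)
  if (!identical(d, c(object@grid@nrows, object@grid@ncols)))
    msg <- c(msg, sprintf("classIds must be a %d x %d matrix",
                          object@grid@nrows, object@grid@ncols))
  if (!is.integer(object@classIds))
    msg <- c(msg, "classIds must be an integer matrix")
  if (length(object@legend) < 1L || is.null(names(object@legend)))
    msg <- c(msg, "legend must be a non-empty named character vector")
  else {
    present <- unique(object@classIds[!is.na(object@classIds)])
    if (!all(as.character(present) %in% names(object@legend)))
      msg <- c(msg, "every class id present in the raster must be in the legend")
  }
  if (length(msg)) msg else TRUE
})

#' Evaluation-unit map
#'
#' The result of overlaying land-use, soil and administrative layers:
#' each farmland cell carries the integer id of the evaluation unit it
#' belongs to (0 = background / non-farmland), and a unit table records
#' each unit's region, soil and land-use class together with its area.
#'
#' @slot grid a [GridSpec-class].
#' @slot labels integer matrix of unit ids; 0 = background.
#' @slot units data.frame with columns \code{unit_id}, \code{region_id},
#'   \code{soil_id}, \code{landuse_id}, \code{n_cells}, \code{area_hm2};
#'   exactly one row per nonzero label.
#'
#' @seealso [buildEvaluationUnits()], [zonalMean()].
#' @export
setClass("UnitMap",
  representation(grid = "GridSpec", labels = "matrix", units = "data.frame")
)

setValidity("UnitMap", function(object) {
  msg <- character()
  d <- dim(object@labels)
  if (!identical(d, c(object@grid@nrows, object@grid@ncols)))
    msg <- c(msg, sprintf("labels must be a %d x %d matrix",
                          object@grid@nrows, object@grid@ncols))
  need <- c("unit_id", "region_id", "soil_id", "landuse_id",
            "n_cells", "area_hm2")
  if (!all(need %in% names(object@units)))
    msg <- c(msg, paste("units table must have columns:",
                        paste(need, collapse = ", ")))
  else {
    lab <- unique(object@labels[object@labels != 0L & !is.na(object@labels)])
    if (!setequal(lab, object@units$unit_id))
      msg <- c(msg, "unit table rows must correspond 1:1 to nonzero labels")
    if (anyDuplicated(object@units$unit_id))
      msg <- c(msg, "duplicated unit_id in unit table")
  }
  if (length(msg)) msg else TRUE
})

#' Fuzzy membership function specification
#'
#' Parameters of one numeric indicator's membership function, mapping a raw
#' indicator value u to a membership degree in [0, 1]:
#' \describe{
#'   \item{decreasing / peak}{\eqn{Y = 1 / (1 + a (u - c)^2)}; \code{c} is
#'     the standard (optimal) value, \code{a > 0} controls the fall-off.}
#'   \item{linear}{\eqn{Y = a u + b}.}
#' }
#' Inputs are clamped to \code{[uLo, uHi]} (the fitted domain) before
#' evaluation and outputs are clamped to [0, 1].
#'
#' @slot indicatorId character indicator id.
#' @slot kind one of \code{"decreasing"}, \code{"peak"}, \code{"linear"}.
#' @slot a,b,c numeric coefficients (\code{b} used only by linear,
#'   \code{c} only by decreasing/peak).
#' @slot uLo,uHi numeric bounds of the indicator domain, \code{uLo < uHi}.
#'
#' @seealso [membershipSpec()], [evaluateMembership()],
#'   [refMembershipSpecs()].
#' @export
setClass("MembershipSpec",
  representation(indicatorId = "character", kind = "character",
                 a = "numeric", b = "numeric", c = "numeric",
                 uLo = "numeric", uHi = "numeric")
)

setValidity("MembershipSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("decreasing", "peak", "linear"))
    msg <- c(msg, "kind must be one of 'decreasing', 'peak', 'linear'")
  if (!isTRUE(object@uLo < object@uHi))
    msg <- c(msg, "uLo must be < uHi")
  if (object@kind %in% c("decreasing", "peak") && !isTRUE(object@a > 0))
    msg <- c(msg, "a must be > 0 for decreasing and peak kinds")
  if (length(msg)) msg else TRUE
})

#' Conceptual (qualitative) indicator scoring scale
#'
#' Expert-assigned membership scores for a qualitative indicator: an
#' ordered list of category names with strictly decreasing scores in
#' (0, 1], the first (best) category scoring 1.
#'
#' @slot indicatorId character indicator id.
#' @slot categories character vector of category names, best first.
#' @slot scores numeric vector of the same length, strictly decreasing,
#'   in (0, 1].
#'
#' @seealso [conceptualScale()], [scoreConceptual()],
#'   [refConceptualScales()].
#' @export
setClass("ConceptualScale",
  representation(indicatorId = "character", categories = "character",
                 scores = "numeric")
)

setValidity("ConceptualScale", function(object) {
  msg <- character()
  if (length(object@categories) != length(object@scores))
    msg <- c(msg, "categories and scores must have equal length")
  if (length(object@scores)) {
    if (any(object@scores <= 0 | object@scores > 1))
      msg <- c(msg, "scores must lie in (0, 1]")
    if (length(object@scores) > 1L && any(diff(object@scores) >= 0))
      msg <- c(msg, "scores must be strictly decreasing along the category order")
  }
  if (anyDuplicated(object@categories))
    msg <- c(msg, "duplicated category names")
  if (length(msg)) msg else TRUE
})

#' Quality-grade classification scheme
#'
#' Contiguous, descending intervals of the comprehensive farmland quality
#' index, one per grade. Grade I holds the highest interval. Classification
#' treats each interval as half-open on its lower bound, \code{[lo, hi)},
#' except the top interval which includes its maximum.
#'
#' @slot labels character grade labels, best first (default Roman I..V).
#' @slot lower,upper numeric interval bounds per grade, in label order
#'   (so \code{upper} is decreasing and \code{lower[k] == upper[k+1]}).
#'
#' @seealso [gradeScheme()], [jenksBreaks()], [classifyGrades()],
#'   [refGradeScheme()].
#' @export
setClass("GradeScheme",
  representation(labels = "character", lower = "numeric", upper = "numeric")
)

setValidity("GradeScheme", function(object) {
  msg <- character()
  k <- length(object@labels)
  if (k < 1L) msg <- c(msg, "at least one grade required")
  if (length(object@lower) != k || length(object@upper) != k)
    msg <- c(msg, "labels, lower and upper must have equal length")
  else {
    # the top interval may collapse to a point (top-inclusive rule);
    # every other grade needs a proper interval
    if (object@lower[1L] > object@upper[1L] ||
        (k > 1L && any(object@lower[-1L] >= object@upper[-1L])))
      msg <- c(msg, "each grade must have lower < upper (top grade: <=)")
    if (k > 1L) {
      if (any(abs(object@lower[-k] - object@upper[-1L]) > 1e-12))
        msg <- c(msg, "intervals must be contiguous (lower[k] == upper[k+1])")
      if (any(diff(object@lower) >= 0))
        msg <- c(msg, "intervals must descend from grade I")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Economic valuation parameters
#'
#' Crop price and production cost (yuan per tonne) and an optional
#' single-year discount rate. The margin \code{price - cost} converts a
#' grade-standard yield (t/hm2) into a per-hectare value (yuan/hm2).
#'
#' @slot price numeric, market price in yuan/t (>= 0).
#' @slot cost numeric, production cost in yuan/t (>= 0).
#' @slot discountRate numeric, dimensionless rate in [0, 1); \code{NA_real_}
#'   when no discounting is requested.
#'
#' @seealso [economicParams()], [unitValue()], [presentValue()].
#' @export
setClass("EconomicParams",
  representation(price = "numeric", cost = "numeric",
                 discountRate = "numeric"),
  prototype(price = 0, cost = 0, discountRate = NA_real_)
)

setValidity("EconomicParams", function(object) {
  msg <- character()
  if (!isTRUE(object@price >= 0)) msg <- c(msg, "price must be >= 0")
  if (!isTRUE(object@cost >= 0)) msg <- c(msg, "cost must be >= 0")
  r <- object@discountRate
  if (!is.na(r) && !(r >= 0 && r < 1))
    msg <- c(msg, "discountRate must be in [0, 1) when present")
  if (length(msg)) msg else TRUE
})

#' Economic valuation report
#'
#' Per-grade unit values (yuan/hm2), per-grade and (optionally) per-region
#' total values (yuan), the grand total, and percentage shares of area and
#' value per grade; optionally a discounted present value.
#'
#' @slot unitValues named numeric, yuan/hm2 per grade.
#' @slot gradeAreas named numeric, hm2 per grade.
#' @slot gradeTotals named numeric, yuan per grade.
#' @slot regionTotals named numeric, yuan per region (may be empty).
#' @slot grandTotal numeric, yuan.
#' @slot areaShares,valueShares named numeric, percentages per grade.
#' @slot presentValue numeric, yuan (\code{NA_real_} if not discounted).
#' @slot params an [EconomicParams-class].
#'
#' @seealso [totalValue()], [valueShares()], [presentValue()].
#' @export
setClass("ValuationReport",
  representation(unitValues = "numeric", gradeAreas = "numeric",
                 gradeTotals = "numeric", regionTotals = "numeric",
                 grandTotal = "numeric", areaShares = "numeric",
                 valueShares = "numeric", presentValue = "numeric",
                 params = "EconomicParams")
)

setValidity("ValuationReport", function(object) {
  msg <- character()
  g <- names(object@unitValues)
  if (is.null(g)) msg <- c(msg, "unitValues must be named by grade")
  if (!identical(names(object@gradeTotals), g) ||
      !identical(names(object@gradeAreas), g))
    msg <- c(msg, "gradeAreas/gradeTotals must share unitValues' grade names")
  if (length(object@grandTotal) != 1L)
    msg <- c(msg, "grandTotal must be a single number")
  else if (is.finite(object@grandTotal) &&
           abs(sum(object@gradeTotals) - object@grandTotal) >
             1e-6 * max(1, abs(object@grandTotal)))
    msg <- c(msg, "grandTotal must equal the sum of gradeTotals")
  if (length(msg)) msg else TRUE
})
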