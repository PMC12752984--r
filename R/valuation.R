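# Economic valuation: per-grade unit values from grade-standard yields,
# aggregation to totals and shares, the single-year discount, and the
# internal-consistency ledger over the bundled reference tables.

#' Per-hectare economic value of a grade
#'
#' \eqn{V_j = MPP_j (p - c)}: the grade-standard yield (t/hm2) times the
#' margin between market price and production cost (yuan/t). A negative
#' margin is allowed with a warning.
#'
#' @param mppJ numeric grade-standard yield(s), t/hm2.
#' @param params an [EconomicParams-class].
#' @return Unit value(s) in yuan/hm2 (names kept).
#' @examples
#' unitValue(10, economicParams(price = 2640, cost = 1760))  # 8800
#' @export
unitValue <- function(mppJ, params) {
  stopifnot(is(params, "EconomicParams"))
  margin <- params@price - params@cost
  if (margin < 0)
    warning(sprintf("negative margin (%g yuan/t): price below production cost",
                    margin))
  mppJ * margin
}

#' Aggregate per-grade values into a valuation report
#'
#' Total value per grade is \eqn{V_j S_j} (unit value times grade area);
#' the grand total is \eqn{V_{total} = \sum_j V_j S_j}. With a
#' region-by-grade area table the per-region totals are also reported.
#' Percentage shares of area and value per grade are included, and a
#' present value is attached when \code{params} carries a discount rate.
#'
#' @param unitValues named numeric, yuan/hm2 per grade.
#' @param areas either a named numeric vector of per-grade areas (hm2) or
#'   a regions x grades matrix such as [tabulateAreas()] returns.
#' @param params an [EconomicParams-class] (recorded in the report; also
#'   supplies the optional discount rate).
#' @return A [ValuationReport-class].
#' @export
totalValue <- function(unitValues, areas,
                       params = economicParams()) {
  if (is.matrix(areas)) {
    gradeAreas <- colSums(areas)
    regionAreas <- areas
  } else {
    gradeAreas <- areas
    regionAreas <- NULL
  }
  grades <- names(gradeAreas)
  if (is.null(grades) || is.null(names(unitValues)))
    stop("unitValues and areas must be named by grade")
  missing <- grades[gradeAreas > 0 & !(grades %in% names(unitValues))]
  miss2 <- grades[gradeAreas > 0 & grades %in% names(unitValues) &
                    is.na(unitValues[grades])]
  missing <- c(missing, miss2)
  if (length(missing))
    stop(sprintf("missing unit value for grade(s) with area: %s",
                 paste(missing, collapse = ", ")))
  uv <- unitValues[grades]
  uv[is.na(uv)] <- 0  # empty grades contribute nothing
  names(uv) <- grades
  gradeTotals <- uv * gradeAreas
  grand <- sum(gradeTotals)
  regionTotals <- if (!is.null(regionAreas))
    stats::setNames(as.vector(regionAreas %*% uv), rownames(regionAreas))
  else numeric(0)
  areaShares <- 100 * gradeAreas / sum(gradeAreas)
  valShares <- if (grand > 0) 100 * gradeTotals / grand
               else stats::setNames(rep(NA_real_, length(grades)), grades)
  pv <- if (!is.na(params@discountRate))
    presentValue(grand, params@discountRate) else NA_real_
  new("ValuationReport", unitValues = uv, gradeAreas = gradeAreas,
      gradeTotals = gradeTotals, regionTotals = regionTotals,
      grandTotal = grand, areaShares = areaShares, valueShares = valShares,
      presentValue = pv, params = params)
}

#' Per-grade value shares
#'
#' Percentage of the grand total contributed by each grade,
#' \eqn{100 V_j S_j / V_{total}}, with optional display rounding.
#'
#' @param report a [ValuationReport-class].
#' @param digits optional rounding for display (NULL = full precision).
#' @return Named numeric percentages summing to 100 (before rounding).
#' @export
valueShares <- function(report, digits = NULL) {
  stopifnot(is(report, "ValuationReport"))
  if (!isTRUE(report@grandTotal > 0)) stop("grand total must be > 0")
  s <- 100 * report@gradeTotals / report@grandTotal
  if (!is.null(digits)) s <- round(s, digits)
  s
}

#' Per-grade unit values from totals and areas
#'
#' The algebraic inverse of [totalValue()]: elementwise quotient of
#' per-grade total values by per-grade areas.
#'
#' @param totals named numeric per-grade totals (yuan).
#' @param areas named numeric per-grade areas (hm2, > 0).
#' @return Named numeric unit values (yuan/hm2).
#' @export
deriveUnitValues <- function(totals, areas) {
  if (any(areas <= 0, na.rm = TRUE)) stop("areas must be > 0")
  totals / areas
}

#' Single-year present value
#'
#' \eqn{PV = V_1 / (1 + r)}: the one-year-ahead value discounted once.
#'
#' @param v1 value one year out (yuan).
#' @param r discount rate (> -1).
#' @return Present value (yuan).
#' @examples
#' presentValue(1363115430.35, 0.03)
#' @export
presentValue <- function(v1, r) {
  if (any(r <= -1)) stop("discount rate must be > -1")
  v1 / (1 + r)
}

#' Internal-consistency ledger over the reference tables
#'
#' Recomputes the aggregation identities of the bundled reference
#' constants and reports each as pass/fail:
#' \itemize{
#'   \item grade-area column sums vs the printed grade totals (within
#'     0.5 hm2 print rounding) and the printed grand total 481473 hm2;
#'   \item region row sums vs the printed region totals;
#'   \item the five per-grade economic totals vs the printed grand total
#'     (within 0.01 yuan);
#'   \item printed unit values x grade areas vs the printed grand total
#'     (relative 1e-5, limited by printed rounding);
#'   \item per-grade unit values recovered from totals / areas;
#'   \item the stated grade-area, regional dominant-grade and value
#'     shares after rounding.
#' }
#'
#' @return A data.frame with columns \code{check}, \code{expected},
#'   \code{actual}, \code{tol}, \code{pass}. Failures are reported, not
#'   raised.
#' @export
consistencyCheck <- function() {
  areas <- refGradeAreas()
  tot <- refGradeAreaTotals()
  econ <- refEconomicValues()
  rows <- list()
  add <- function(check, expected, actual, tol) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, expected = expected, actual = actual, tol = tol,
      pass = abs(actual - expected) <= tol)
  }
  cs <- colSums(areas)
  for (g in colnames(areas))
    add(sprintf("grade %s area total (hm2)", g), tot$grades[g], cs[g], 0.5)
  add("grand area total (hm2)", tot$grand, sum(areas), 0.5)
  rs <- rowSums(areas)
  for (r in rownames(areas))
    add(sprintf("region %s area total (hm2)", r), tot$regions[r], rs[r], 0.5)
  add("economic grand total (yuan)", econ$grand, sum(econ$gradeTotals), 0.01)
  vxs <- sum(econ$unitValues * tot$grades)
  add("unit values x grade areas vs grand total (yuan)", econ$grand, vxs,
      1e-5 * econ$grand)
  uv <- deriveUnitValues(econ$gradeTotals, tot$grades)
  for (g in names(uv))
    add(sprintf("grade %s unit value from totals (yuan/hm2)", g),
        econ$unitValues[g], round(uv[g], 2), 0.005)
  # stated shares
  add("grade I area share (%, integer)", 5,
      round(100 * tot$grades["I"] / sum(tot$grades)), 0)
  add("grade V area share (%, integer)", 33,
      round(100 * tot$grades["V"] / sum(tot$grades)), 0)
  dom <- c(Baohe = 63, Shushan = 75, Lujiang = 49, Changfeng = 36)
  domGrade <- c(Baohe = "V", Shushan = "IV", Lujiang = "IV",
                Changfeng = "IV")
  for (r in names(dom))
    add(sprintf("%s dominant-grade share (%%, integer)", r), dom[[r]],
        round(100 * areas[r, domGrade[[r]]] / rs[r]), 0)
  shares <- 100 * econ$gradeTotals / sum(econ$gradeTotals)
  add("grade II value share (%, 1 dp)", 11.6, round(shares["II"], 1), 0)
  add("grade V value share (%, integer)", 30, round(shares["V"]), 0)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
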