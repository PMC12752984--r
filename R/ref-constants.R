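# Bundled reference constants from the published Hefei (Anhui, China)
# farmland-valuation case study: indicator weights, fitted membership
# functions, expert conceptual scores, grade thresholds, per-region grade
# areas, grade-standard yields and economic values. They serve as defaults
# for the pipeline and as fixtures for the internal consistency checks.
# All values are verbatim as printed; no renormalisation is applied unless
# requested.

#' Reference indicator metadata
#'
#' The 16 natural-attribute indicators of the Hefei case study: id, short
#' name, whether the indicator is numeric (scored by a fitted membership
#' function) or conceptual (scored by an expert lookup scale), and its
#' AHP weight.
#'
#' @return A data.frame with columns \code{id}, \code{name}, \code{type}
#'   (\code{"continuous"} or \code{"conceptual"}) and \code{weight}.
#' @seealso [refWeights()], [refMembershipSpecs()], [refConceptualScales()]
#' @export
refIndicators <- function() {
  data.frame(
    id = paste0("I", 1:16),
    name = c("topographic_area", "slope", "texture", "bulk_density",
             "gravel_volume", "effective_water", "fragmentation", "ph",
             "organic_matter", "cation_exchange", "organic_carbon",
             "total_nitrogen", "dist_water", "dist_settlement",
             "water_conservation", "soil_retention"),
    type = c("conceptual", "continuous", "conceptual", "continuous",
             "continuous", "continuous", "continuous", "continuous",
             "continuous", "continuous", "continuous", "continuous",
             "conceptual", "conceptual", "conceptual", "conceptual"),
    weight = c(0.1191, 0.2381, 0.0632, 0.0309, 0.0188, 0.0442, 0.0173,
               0.0434, 0.0819, 0.0434, 0.0756, 0.0264, 0.0426, 0.0426,
               0.0562, 0.0562),
    stringsAsFactors = FALSE
  )
}

#' Reference AHP weight vector
#'
#' The published combined weights of the 16 indicators. As printed they
#' sum to 0.9999; by default they are returned verbatim.
#'
#' @param renormalise logical; if TRUE, rescale to sum exactly 1.
#' @return Named numeric vector (names I1..I16).
#' @examples
#' sum(refWeights())        # 0.9999 as printed
#' refWeights()["I2"]       # slope carries the largest weight
#' @export
refWeights <- function(renormalise = FALSE) {
  ind <- refIndicators()
  w <- stats::setNames(ind$weight, ind$id)
  if (renormalise) w <- w / sum(w)
  w
}

#' Reference membership-function specifications
#'
#' The ten fitted numeric membership functions (decreasing, peak and
#' linear kinds) with their coefficients and indicator-domain bounds.
#'
#' Two printed quirks are kept as printed and only flagged here: the pH
#' row is labelled peak-type but has standard value c = 0, which makes it
#' monotone decreasing over its domain [5.4, 7.2]; and the
#' effective-water linear function (a = 0.0015, b = 0) tops out near
#' 0.055 over its printed bounds, which looks like a units inconsistency
#' in the source. Both are reproduced verbatim.
#'
#' @return Named list of [MembershipSpec-class] objects, named by
#'   indicator id.
#' @export
refMembershipSpecs <- function() {
  s <- list(
    membershipSpec("I2", "decreasing", a = 0.0157, c = 0,
                   uLo = 0, uHi = 28.0476),
    membershipSpec("I7", "decreasing", a = 0.0282, c = 0.2393,
                   uLo = 0, uHi = 16.9944),
    membershipSpec("I5", "decreasing", a = 0.0055, c = 1.2537,
                   uLo = 5.66, uHi = 19.3860),
    membershipSpec("I4", "peak", a = 57.0546, c = 1.2597,
                   uLo = 1.21, uHi = 1.5),
    membershipSpec("I8", "peak", a = 0.0034, c = 0,
                   uLo = 5.4, uHi = 7.2),
    membershipSpec("I9", "linear", a = 0.0417, b = -0.343143,
                   uLo = 8.9648, uHi = 32.2732),
    membershipSpec("I10", "linear", a = 0.0120, b = -1.735604,
                   uLo = 138.7333, uHi = 228.4375),
    membershipSpec("I11", "linear", a = 0.0482, b = 0,
                   uLo = 0, uHi = 22.4),
    membershipSpec("I12", "linear", a = 1.1069, b = -0.72424,
                   uLo = 0.72, uHi = 1.81),
    membershipSpec("I6", "linear", a = 0.0015, b = 0,
                   uLo = 27.2, uHi = 36.8200)
  )
  stats::setNames(s, vapply(s, function(x) x@indicatorId, character(1)))
}

#' Reference conceptual scoring scales
#'
#' Expert (Delphi) membership scores for the six qualitative indicators.
#' The printed criteria table lists each row's categories without an
#' explicit column alignment; the adopted convention is that each row's
#' categories occupy consecutive score columns starting at 1.0
#' (topography 1.0 to 0.4 over 7 classes, texture 1.0 to 0.3 over 8,
#' five-level rows 1.0 to 0.6). "Closer" is best for both distance
#' indicators, reflecting irrigation and cultivation convenience.
#'
#' @return Named list of [ConceptualScale-class] objects, named by
#'   indicator id.
#' @export
refConceptualScales <- function() {
  s <- list(
    conceptualScale("I1",
      c("Impact plains", "Alluvial fan plains", "Lacustrine plains",
        "Flood plains", "Storm mesa", "Flood mesas",
        "Small undulating mountainous terrain"),
      seq(1.0, 0.4, by = -0.1)),
    conceptualScale("I3",
      c("Tsubado", "Clay loam soil", "Silty loam", "Sandy loam", "Clay",
        "Heavy clay", "Loamy sandy soil", "Sandy soil"),
      seq(1.0, 0.3, by = -0.1)),
    conceptualScale("I13",
      c("Closer", "Close", "Moderate", "Far", "Farther"),
      seq(1.0, 0.6, by = -0.1)),
    conceptualScale("I14",
      c("Closer", "Close", "Moderate", "Far", "Farther"),
      seq(1.0, 0.6, by = -0.1)),
    conceptualScale("I15",
      c("Stronger", "Strong ability", "Moderate", "Weak", "Weaker"),
      seq(1.0, 0.6, by = -0.1)),
    conceptualScale("I16",
      c("Stronger", "Strong ability", "Moderate", "Weak", "Weaker"),
      seq(1.0, 0.6, by = -0.1))
  )
  stats::setNames(s, vapply(s, function(x) x@indicatorId, character(1)))
}

#' Reference grade schemes
#'
#' Two threshold sets for cutting the quality index into five grades
#' circulate in the case study's report. The \code{"canonical"} set is
#' the one that accompanies the published grade areas and is used for all
#' consistency checks; the \code{"alternate"} set appears in the methods
#' narrative and is kept as a named fixture.
#'
#' @param which \code{"canonical"} (default) or \code{"alternate"}.
#' @return A [GradeScheme-class] with five grades I..V.
#' @examples
#' classifyGrades(c(0.70, 0.6477, 0.6476), refGradeScheme())
#' @export
refGradeScheme <- function(which = c("canonical", "alternate")) {
  which <- match.arg(which)
  if (which == "canonical")
    gradeScheme(lower = c(0.6477, 0.6078, 0.5773, 0.5327, 0.3962),
                upper = c(0.7499, 0.6477, 0.6078, 0.5773, 0.5327))
  else
    gradeScheme(lower = c(0.6477, 0.5738, 0.4991, 0.4186, 0.2840),
                upper = c(0.7499, 0.6477, 0.5738, 0.4991, 0.4186))
}

#' Reference per-region grade areas (hm2)
#'
#' The published farmland area by quality grade across the nine
#' administrative regions of Hefei, in hm2, as printed (rounded to two
#' decimals). Row and column sums agree with the printed marginal totals
#' to within print rounding (at most 0.43 hm2 on one row).
#'
#' @return A 9 x 5 numeric matrix, regions x grades I..V.
#' @seealso [refGradeAreaTotals()], [consistencyCheck()]
#' @export
refGradeAreas <- function() {
  m <- matrix(c(
    45.41,    323.23,   653.02,   340.55,   2306.83,
    2493.1,   4134.98,  15500.8,  18479.64, 29128.09,
    3685.99,  19874.53, 12608.84, 17571.45, 58758.1,
    62.51,    1880.58,  13654.03, 18285.95, 42121.82,
    1589.93,  8896.8,   16834.84, 50363.67, 24121.19,
    98.61,    870.89,   800.67,   367.54,   511.37,
    26.49,    627.8,    3853.98,  16257.79, 941.65,
    7.27,     232.07,   1245.03,  1721.62,  825.23,
    16682.9,  12809.54, 26331.97, 32225.8,  1319.2
  ), nrow = 9, byrow = TRUE)
  dimnames(m) <- list(
    c("Baohe", "Chaohu", "Feidong", "Feixi", "Lujiang", "Luyang",
      "Shushan", "Yaohai", "Changfeng"),
    c("I", "II", "III", "IV", "V"))
  m
}

#' Printed marginal totals of the reference grade-area table
#'
#' @return A list with \code{grades} (printed per-grade totals, hm2),
#'   \code{regions} (printed per-region totals, hm2) and \code{grand}
#'   (printed grand total, hm2).
#' @export
refGradeAreaTotals <- function() {
  list(
    grades = stats::setNames(
      c(24692.2, 49650.41, 91483.2, 155614, 160033.49),
      c("I", "II", "III", "IV", "V")),
    regions = stats::setNames(
      c(3669.04, 69736.6, 112499, 76004.9, 101806, 2649.08, 21707.7,
        4031.21, 89369.4),
      rownames(refGradeAreas())),
    grand = 481473
  )
}

#' Reference grade-standard yields (t/hm2)
#'
#' The published standard production potential per grade. These depend on
#' the real Hefei climate and quality rasters and are fixtures, not
#' quantities the synthetic pipeline reproduces.
#'
#' @return Named numeric vector, grades I..V.
#' @export
refGradeYields <- function() {
  stats::setNames(c(10.28, 9.94, 9.31, 8.91, 7.95), c("I", "II", "III", "IV", "V"))
}

#' Reference per-grade economic values
#'
#' The published per-hectare unit values (yuan/hm2), per-grade totals
#' (yuan) and grand total (yuan). Note that the printed unit values are
#' not reproduced by the valuation formula with the printed yields and
#' margin (10.28 t/hm2 x 880 yuan/t = 9046.4, not 3291.13); the implied
#' effective margin is about 320.15 yuan/t. The constants are therefore
#' used only in aggregation-identity checks, never as a formula target.
#'
#' @return A list with \code{unitValues} (yuan/hm2, grades I..V),
#'   \code{gradeTotals} (yuan), and \code{grand} (yuan).
#' @export
refEconomicValues <- function() {
  list(
    unitValues = stats::setNames(
      c(3291.13, 3181.62, 2983.61, 2851.69, 2544.27),
      c("I", "II", "III", "IV", "V")),
    gradeTotals = stats::setNames(
      c(81265207.27, 157968737.46, 272950190.35, 443762887.66,
        407168407.60),
      c("I", "II", "III", "IV", "V")),
    grand = 1363115430.35
  )
}

#' Reference economic parameters
#'
#' Season-averaged rice market price (2640 yuan/t) and production cost
#' (1760 yuan/t) for the study year.
#'
#' @return An [EconomicParams-class].
#' @export
refEconomicParams <- function() {
  economicParams(price = 2640, cost = 1760)
}
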