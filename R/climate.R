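# Thornthwaite Memorial climatic production potential and its correction
# by the farmland quality index into grade-standard yields.

#' Annual maximum evapotranspiration
#'
#' \eqn{L = 0.05 T^3 + 25 T + 300}, with T the annual mean temperature in
#' degrees Celsius and L in mm. Strictly increasing in T.
#'
#' @param t numeric vector or matrix of annual mean temperature (degC).
#' @return L in mm, same shape as the input.
#' @examples
#' maxEvapotranspiration(c(0, 10, 16))  # 300, 600, 904.8
#' @export
maxEvapotranspiration <- function(t) {
  0.05 * t^3 + 25 * t + 300
}

#' Annual actual evapotranspiration
#'
#' \eqn{V = 1.05 R / \sqrt{1 + (1.05 R / L)^2}}, with R the annual
#' precipitation (mm) and L the annual maximum evapotranspiration (mm).
#' V is strictly increasing in R, bounded by \eqn{\min(1.05 R, L)}, and
#' approaches L as R grows large.
#'
#' @param r numeric annual precipitation (mm, >= 0); recycled against
#'   \code{l}.
#' @param l numeric annual maximum evapotranspiration (mm, > 0).
#' @return V in mm.
#' @export
actualEvapotranspiration <- function(r, l) {
  if (any(r < 0, na.rm = TRUE)) stop("precipitation R must be >= 0")
  if (any(l <= 0, na.rm = TRUE)) stop("L must be > 0")
  x <- 1.05 * r
  x / sqrt(1 + (x / l)^2)
}

#' Climatic production potential (Thornthwaite Memorial)
#'
#' \eqn{NPP_T = 3000 (1 - e^{-0.0009695 (V - 20)})} in g/m2, driven by
#' the annual actual evapotranspiration V (mm). The formula is negative
#' for V < 20 mm and is floored at 0 there; the supremum 3000 g/m2 is
#' approached but never attained.
#'
#' @param v numeric annual actual evapotranspiration (mm).
#' @return NPP in g/m2, in [0, 3000).
#' @examples
#' climaticNPP(20)      # 0
#' climaticNPP(685.4)   # about 1426 g/m2
#' @export
climaticNPP <- function(v) {
  pmax(0, 3000 * (1 - exp(-0.0009695 * (v - 20))))
}

#' Unit conversion between g/m2 and t/hm2
#'
#' 1 g/m2 = 0.01 t/hm2; the round trip is the identity.
#'
#' @param npp numeric NPP in g/m2 (>= 0).
#' @return t/hm2.
#' @export
nppToTonnesPerHa <- function(npp) {
  if (any(npp < 0, na.rm = TRUE)) stop("npp must be >= 0")
  npp * 0.01
}

#' @rdname nppToTonnesPerHa
#' @param t_hm2 numeric NPP in t/hm2.
#' @export
tonnesPerHaToNpp <- function(t_hm2) {
  t_hm2 * 100
}

#' Quality-corrected production potential
#'
#' \eqn{MPP = IFI \times NPP_T}: the climatic potential attenuated by
#' the comprehensive quality index, elementwise. Since IFI is in [0, 1],
#' MPP never exceeds the climatic potential.
#'
#' @param ifi numeric vector/matrix of quality-index values in [0, 1].
#' @param nppT numeric vector/matrix of climatic potential (t/hm2),
#'   same shape (or scalar).
#' @return MPP in the units of \code{nppT}.
#' @export
modifiedPotential <- function(ifi, nppT) {
  if (any(ifi < 0 | ifi > 1, na.rm = TRUE))
    stop("IFI must lie in [0, 1]")
  if (length(ifi) != length(nppT) && length(ifi) != 1L && length(nppT) != 1L)
    stop("shape mismatch between IFI and NPP")
  ifi * nppT
}

#' Grade-standard yields
#'
#' The standard production potential of each grade: the area-weighted
#' mean MPP over the evaluation units of that grade (plain mean with
#' \code{weighted = FALSE}). A grade with no units is flagged absent
#' (NA), never reported as zero.
#'
#' @param mpp named numeric per-unit MPP (t/hm2).
#' @param grades factor of per-unit grades (same order/names as
#'   \code{mpp}).
#' @param areas numeric per-unit areas (hm2), same order.
#' @param weighted logical; area-weighted mean (default) or unweighted.
#' @return Named numeric vector of MPP_j per grade label, NA for empty
#'   grades.
#' @export
gradeStandardYield <- function(mpp, grades, areas, weighted = TRUE) {
  stopifnot(length(mpp) == length(grades), length(mpp) == length(areas))
  if (anyNA(mpp)) stop("every graded unit must have an MPP value")
  lv <- levels(grades)
  out <- stats::setNames(rep(NA_real_, length(lv)), lv)
  for (g in lv) {
    sel <- !is.na(grades) & grades == g
    if (!any(sel)) next
    out[g] <- if (weighted) sum(mpp[sel] * areas[sel]) / sum(areas[sel])
              else mean(mpp[sel])
  }
  out
}
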