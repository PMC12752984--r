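# Indicator scoring: fuzzy membership functions for numeric indicators and
# expert lookup scales for conceptual ones.

#' Score layer
#'
#' An [IndicatorLayer-class] whose values are membership scores in
#' [0, 1] (NA = nodata).
#'
#' @seealso [scoreLayer()]
#' @export
setClass("ScoreLayer", contains = "IndicatorLayer")

setValidity("ScoreLayer", function(object) {
  v <- object@values
  if (any(v < 0 | v > 1, na.rm = TRUE))
    "all non-nodata scores must lie in [0, 1]" else TRUE
})

#' Evaluate a fuzzy membership function
#'
#' Maps raw indicator values to membership degrees. The input is first
#' clamped to the spec's domain \code{[uLo, uHi]} (the bounds delimit the
#' fitted domain), then
#' \itemize{
#'   \item decreasing / peak: \eqn{Y = 1 / (1 + a (u - c)^2)},
#'   \item linear: \eqn{Y = a u + b},
#' }
#' and the result is clamped to [0, 1] (linear fits can stray slightly
#' outside the unit interval at the domain edges; membership is by
#' definition bounded).
#'
#' @param spec a [MembershipSpec-class].
#' @param u numeric vector of raw indicator values (NA passed through).
#' @return Numeric vector of scores in [0, 1].
#' @examples
#' slope <- refMembershipSpecs()[["I2"]]
#' evaluateMembership(slope, c(0, 10, 28.0476))
#' @export
evaluateMembership <- function(spec, u) {
  stopifnot(is(spec, "MembershipSpec"))
  if (!all(is.finite(u) | is.na(u))) stop("u must be finite (or NA)")
  u <- clamp(u, spec@uLo, spec@uHi)
  y <- switch(spec@kind,
    decreasing = ,
    peak = 1 / (1 + spec@a * (u - spec@c)^2),
    linear = spec@a * u + spec@b,
    stop(sprintf("unknown membership kind '%s'", spec@kind))
  )
  clamp(y, 0, 1)
}

#' Score a conceptual indicator category
#'
#' @param scale a [ConceptualScale-class].
#' @param category character vector of category names.
#' @return Numeric scores; unknown categories raise an error listing the
#'   legal ones.
#' @examples
#' topo <- refConceptualScales()[["I1"]]
#' scoreConceptual(topo, "Impact plains")  # 1.0
#' @export
scoreConceptual <- function(scale, category) {
  stopifnot(is(scale, "ConceptualScale"))
  idx <- match(category, scale@categories)
  bad <- !is.na(category) & is.na(idx)
  if (any(bad))
    stop(sprintf("unknown category '%s' for indicator %s; legal categories: %s",
                 category[bad][1L], scale@indicatorId,
                 paste(scale@categories, collapse = ", ")))
  scale@scores[idx]
}

#' Score a whole layer
#'
#' Vectorised per-cell application of [evaluateMembership()] (continuous
#' layers scored by a [MembershipSpec-class]) or [scoreConceptual()]
#' (categorical layers scored by a [ConceptualScale-class], matched
#' through the layer legend's category names). Nodata cells stay NA.
#'
#' @param spec a [MembershipSpec-class] or [ConceptualScale-class].
#' @param layer the matching [IndicatorLayer-class] or
#'   [CategoricalLayer-class].
#' @return A [ScoreLayer-class].
#' @export
setGeneric("scoreLayer", function(spec, layer) standardGeneric("scoreLayer"))

#' @rdname scoreLayer
setMethod("scoreLayer", signature("MembershipSpec", "IndicatorLayer"),
  function(spec, layer) {
    if (is(layer, "CategoricalLayer"))
      stop("kind mismatch: a MembershipSpec scores continuous layers")
    v <- evaluateMembership(spec, layer@values)
    dim(v) <- dim(layer@values)
    new("ScoreLayer", grid = layer@grid, indicatorId = spec@indicatorId,
        values = v)
  })

#' @rdname scoreLayer
setMethod("scoreLayer", signature("ConceptualScale", "CategoricalLayer"),
  function(spec, layer) {
    cats <- layer@legend[as.character(layer@classIds)]
    v <- scoreConceptual(spec, cats)
    dim(v) <- dim(layer@classIds)
    new("ScoreLayer", grid = layer@grid, indicatorId = spec@indicatorId,
        values = v)
  })

#' @rdname scoreLayer
setMethod("scoreLayer", signature("ConceptualScale", "IndicatorLayer"),
  function(spec, layer)
    stop("kind mismatch: a ConceptualScale scores categorical layers"))

#' @rdname scoreLayer
setMethod("scoreLayer", signature("MembershipSpec", "CategoricalLayer"),
  function(spec, layer)
    stop("kind mismatch: a MembershipSpec scores continuous layers"))
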