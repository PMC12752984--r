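# Whole-landscape generation: the bundle of 16 indicator layers, climate
# layers, overlay layers and evaluation units that the pipeline consumes.

#' Landscape generator configuration
#'
#' Ranges and scales of the synthetic landscape. Continuous indicator
#' ranges default to the fitted membership domains of the reference case
#' study, so generated rasters span exactly the domains the scoring
#' functions were fitted on. Climate defaults (annual mean temperature
#' 15-17 degC, annual precipitation 900-1100 mm) are plausible for a
#' subtropical monsoon setting; they are configuration, not reference
#' values.
#'
#' @param nrows,ncols grid dimensions (default 100 x 100).
#' @param cellSize cell size in metres (default 30).
#' @param corrLength correlation length of continuous fields, metres.
#' @param climateCorrLength correlation length of the climate fields,
#'   metres (climate varies on broader scales).
#' @param patchScale characteristic categorical patch diameter, metres.
#' @param tRange,rRange numeric length-2 ranges for temperature (degC)
#'   and precipitation (mm).
#' @param indicatorRanges named list of length-2 numeric ranges for
#'   continuous indicators, overriding the membership-domain defaults.
#' @param minAreaHm2 sliver-elimination threshold for evaluation units.
#' @return A named list (class \code{"landscapeConfig"}).
#' @export
landscapeConfig <- function(nrows = 100, ncols = 100, cellSize = 30,
                            corrLength = 300, climateCorrLength = 1500,
                            patchScale = 300,
                            tRange = c(15, 17), rRange = c(900, 1100),
                            indicatorRanges = list(),
                            minAreaHm2 = 0.36) {
  specs <- refMembershipSpecs()
  ranges <- lapply(specs, function(s) c(s@uLo, s@uHi))
  ranges[names(indicatorRanges)] <- indicatorRanges
  structure(list(nrows = nrows, ncols = ncols, cellSize = cellSize,
                 corrLength = corrLength,
                 climateCorrLength = climateCorrLength,
                 patchScale = patchScale, tRange = tRange, rRange = rRange,
                 indicatorRanges = ranges, minAreaHm2 = minAreaHm2),
            class = "landscapeConfig")
}

#' Generate a complete synthetic landscape
#'
#' Produces a self-consistent bundle on one grid: the 16 indicator
#' layers (continuous autocorrelated fields spanning the membership
#' domains; categorical patch maps whose legends match the conceptual
#' scoring scales), annual temperature and precipitation fields, the
#' land-use / soil / administrative overlay layers, and the evaluation
#' units built from their overlay. The two locational indicators are
#' derived the way a GIS workflow would: Euclidean distance to the
#' nearest water (or settlement) cell of the land-use map, cut into five
#' 500 m buffer rings. On grids too small to contain water or settlement
#' cells the distance is taken as zero (innermost ring). At least one
#' farmland cell is always present.
#'
#' Sub-layers draw from independent seeds derived from the single bundle
#' seed, so the bundle is bit-identical for identical (config, seed).
#'
#' @param config a [landscapeConfig()].
#' @param seed integer seed.
#' @return A list with elements \code{grid}, \code{indicators} (named
#'   list I1..I16), \code{temperature}, \code{precipitation},
#'   \code{landuse}, \code{soil}, \code{admin}, \code{units},
#'   \code{config}, \code{seed}.
#' @examples
#' land <- generateLandscape(landscapeConfig(nrows = 30, ncols = 30), seed = 42)
#' land$units
#' @export
generateLandscape <- function(config = landscapeConfig(), seed = 1) {
  grid <- gridSpec(config$nrows, config$ncols, config$cellSize)
  subSeeds <- withSeed(seed, sample.int(.Machine$integer.max, 32L))
  ind <- refIndicators()
  scales <- refConceptualScales()
  layers <- vector("list", 16L)
  names(layers) <- ind$id
  si <- 0L
  nextSeed <- function() {
    si <<- si + 1L
    subSeeds[si]
  }
  # continuous indicators
  for (id in ind$id[ind$type == "continuous"]) {
    rg <- config$indicatorRanges[[id]]
    layers[[id]] <- generateField(grid, rg[1], rg[2],
                                  corrLength = config$corrLength,
                                  seed = nextSeed(), indicatorId = id)
  }
  # conceptual patch indicators (not distance-derived)
  for (id in c("I1", "I3", "I15", "I16")) {
    sc <- scales[[id]]
    layers[[id]] <- generateCategorical(grid, sc@categories,
                                        patchScale = config$patchScale,
                                        seed = nextSeed(), indicatorId = id)
  }
  # overlay layers
  landuse <- generateCategorical(
    grid, c("farmland", "forest", "water", "settlement"),
    patchScale = config$patchScale, seed = nextSeed(),
    indicatorId = "landuse")
  # the pipeline needs farmland; pin the central cell if absent
  cls <- landuse@classIds
  if (!any(cls == 1L, na.rm = TRUE)) {
    cls[ceiling(grid@nrows / 2), ceiling(grid@ncols / 2)] <- 1L
    landuse <- categoricalLayer(grid, cls, landuse@legend, "landuse")
  }
  soil <- generateCategorical(grid, paste0("soil_", 1:6),
                              patchScale = config$patchScale * 2,
                              seed = nextSeed(), indicatorId = "soil")
  admin <- generateCategorical(grid, paste0("region_", 1:4),
                               patchScale = config$patchScale * 4,
                               seed = nextSeed(), indicatorId = "admin")
  # locational indicators via distance + buffer rings
  ringLayer <- function(targetClass, id) {
    if (any(landuse@classIds == targetClass, na.rm = TRUE)) {
      d <- distanceTransform(landuse, targetClass, indicatorId = id)
    } else {
      d <- indicatorLayer(grid, matrix(0, grid@nrows, grid@ncols), id)
    }
    ringClassify(d, ringWidth = 500, nRings = 5,
                 legendNames = scales[[id]]@categories, indicatorId = id)
  }
  layers[["I13"]] <- ringLayer(3L, "I13")  # water
  layers[["I14"]] <- ringLayer(4L, "I14")  # settlements
  temperature <- generateField(grid, config$tRange[1], config$tRange[2],
                               corrLength = config$climateCorrLength,
                               seed = nextSeed(), indicatorId = "T")
  precipitation <- generateField(grid, config$rRange[1], config$rRange[2],
                                 corrLength = config$climateCorrLength,
                                 seed = nextSeed(), indicatorId = "R")
  units <- buildEvaluationUnits(landuse, soil, admin,
                                minAreaHm2 = config$minAreaHm2,
                                farmlandClasses = 1L)
  list(grid = grid, indicators = layers, temperature = temperature,
       precipitation = precipitation, landuse = landuse, soil = soil,
       admin = admin, units = units, config = config, seed = seed)
}
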