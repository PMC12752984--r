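# Plain-text raster and table I/O. Rasters travel as Esri ASCII grids
# (single band, nodata tagged, full-precision values so round trips are
# exact); tables as CSV.

#' Write a layer as an Esri ASCII grid
#'
#' Single-band plain-text raster with the standard six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed
#' by rows from north to south. Values are written with 17 significant
#' digits, so a write/read round trip reproduces the layer exactly.
#'
#' @param layer an [IndicatorLayer-class] or [CategoricalLayer-class].
#' @param path output file path.
#' @param nodata nodata sentinel written for NA cells (default -9999).
#' @return \code{path}, invisibly.
#' @seealso [readAsciiGrid()]
#' @export
writeAsciiGrid <- function(layer, path, nodata = -9999) {
  g <- gridOf(layer)
  v <- layerValues(layer)
  if (any(v == nodata, na.rm = TRUE))
    stop("nodata sentinel collides with a data value; choose another")
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g@ncols),
    sprintf("nrows %d", g@nrows),
    sprintf("xllcorner %.17g", g@originX),
    sprintf("yllcorner %.17g", g@originY - g@nrows * g@cellSize),
    sprintf("cellsize %.17g", g@cellSize),
    sprintf("NODATA_value %.17g", nodata)
  ), con)
  writeLines(apply(v, 1L, function(row)
    paste(sprintf("%.17g", row), collapse = " ")), con)
  invisible(path)
}

#' Read an Esri ASCII grid
#'
#' @param path input file path.
#' @param indicatorId id for the returned layer.
#' @param categorical logical; if TRUE return a
#'   [CategoricalLayer-class] (a legend is synthesised from the distinct
#'   ids unless supplied).
#' @param legend optional named character legend for categorical reads.
#' @param crsTag CRS label to attach.
#' @return An [IndicatorLayer-class] or [CategoricalLayer-class].
#' @export
readAsciiGrid <- function(path, indicatorId = "I", categorical = FALSE,
                          legend = NULL, crsTag = "local-metric") {
  lines <- readLines(path)
  hdr <- list()
  i <- 0L
  while (i < length(lines)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1L]]
    if (length(parts) == 2L &&
        tolower(parts[1L]) %in% c("ncols", "nrows", "xllcorner",
                                  "yllcorner", "cellsize", "nodata_value")) {
      hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header (need ncols/nrows/llcorner/cellsize)")
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[(i + 1L):length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d cells, found %d", nr * nc, length(vals)))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  grid <- gridSpec(nr, nc, hdr$cellsize, originX = hdr$xllcorner,
                   originY = hdr$yllcorner + nr * hdr$cellsize,
                   crsTag = crsTag)
  if (categorical) {
    if (is.null(legend)) {
      ids <- sort(unique(m[!is.na(m)]))
      legend <- stats::setNames(paste("class", ids), as.character(ids))
    }
    categoricalLayer(grid, m, legend, indicatorId)
  } else {
    indicatorLayer(grid, m, indicatorId)
  }
}

#' Write / read the evaluation-unit table as CSV
#'
#' @param units a [UnitMap-class] (write) or CSV path (read).
#' @param path output path.
#' @return The unit data.frame, invisibly for the writer.
#' @export
writeUnitTable <- function(units, path) {
  stopifnot(is(units, "UnitMap"))
  utils::write.csv(units@units, path, row.names = FALSE)
  invisible(units@units)
}

#' @rdname writeUnitTable
#' @export
readUnitTable <- function(path) {
  utils::read.csv(path)
}
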