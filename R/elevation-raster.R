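#' @include AllClasses.R
NULL

#' Construct an ElevationRaster
#'
#' @param values numeric matrix of elevations (metres), row 1 = north.
#'   Cells equal to \code{nodata} are converted to \code{NA}.
#' @param origin numeric(2): x, y of the upper-left grid corner.
#' @param cellSize cell edge length (metres, or degrees in geographic
#'   mode).
#' @param nodata nodata sentinel used on disk (default -9999).
#' @param crsMode \code{"projected"} or \code{"geographic"}.
#' @return An [ElevationRaster-class] object.
#' @examples
#' r <- ElevationRaster(matrix(1:12, 3, 4), origin = c(0, 3), cellSize = 1)
#' dim(r)
#' @export
ElevationRaster <- function(values, origin = c(0, nrow(values)),
                            cellSize = 1, nodata = -9999,
                            crsMode = c("projected", "geographic")) {
  crsMode <- match.arg(crsMode)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.finite(nodata)) values[values == nodata] <- NA_real_
  methods::new("ElevationRaster", values = values,
               origin = as.numeric(origin), cellSize = as.numeric(cellSize),
               nodata = as.numeric(nodata), crsMode = crsMode)
}

#' @describeIn ElevationRaster Grid of values (\code{NA} = nodata).
#' @param x an \code{ElevationRaster}.
#' @export
setMethod("rasterValues", "ElevationRaster", function(x) x@values)

#' @describeIn ElevationRaster Upper-left corner coordinate.
#' @export
setMethod("rasterOrigin", "ElevationRaster", function(x) x@origin)

#' @describeIn ElevationRaster Cell edge length.
#' @export
setMethod("cellSize", "ElevationRaster", function(x) x@cellSize)

#' @describeIn ElevationRaster Nodata sentinel used on disk.
#' @export
setMethod("nodataValue", "ElevationRaster", function(x) x@nodata)

#' @describeIn ElevationRaster Coordinate mode.
#' @export
setMethod("crsMode", "ElevationRaster", function(x) x@crsMode)

#' @export
setMethod("dim", "ElevationRaster", function(x) dim(x@values))

setMethod("show", "ElevationRaster", function(object) {
  d <- dim(object@values)
  v <- object@values[!is.na(object@values)]
  cat("ElevationRaster:", d[1], "rows x", d[2], "cols,",
      "cell", object@cellSize,
      if (object@crsMode == "projected") "m," else "deg,",
      object@crsMode, "\n")
  cat("  origin (UL corner):", object@origin[1], ",", object@origin[2], "\n")
  if (length(v)) {
    cat(sprintf("  elevation: %.1f .. %.1f (mean %.1f, sd %.2f), %d nodata\n",
                min(v), max(v), mean(v), stats::sd(v),
                sum(is.na(object@values))))
  } else cat("  all cells nodata\n")
})

# x coordinates of cell centers, column-wise
cellCenterX <- function(r) {
  r@origin[1] + (seq_len(ncol(r@values)) - 0.5) * r@cellSize
}

# y coordinates of cell centers, row-wise (row 1 = north, decreasing y)
cellCenterY <- function(r) {
  r@origin[2] - (seq_len(nrow(r@values)) - 0.5) * r@cellSize
}

# footprint: xmin, xmax, ymin, ymax of the grid (cell edges)
rasterFootprint <- function(r) {
  d <- dim(r@values)
  c(xmin = r@origin[1], xmax = r@origin[1] + d[2] * r@cellSize,
    ymin = r@origin[2] - d[1] * r@cellSize, ymax = r@origin[2])
}

# nearest-cell elevation at point coordinates (vectorized); NA outside
elevationAt <- function(r, x, y) {
  j <- floor((x - r@origin[1]) / r@cellSize) + 1L
  i <- floor((r@origin[2] - y) / r@cellSize) + 1L
  d <- dim(r@values)
  ok <- i >= 1L & i <= d[1] & j >= 1L & j <= d[2] & is.finite(x) & is.finite(y)
  out <- rep(NA_real_, length(x))
  out[ok] <- r@values[cbind(i[ok], j[ok])]
  out
}
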