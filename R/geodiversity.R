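#' @include elevation-raster.R
NULL

#' Elevation values inside a circular window
#'
#' Returns the values of all non-nodata cells whose center lies at
#' distance <= radius from the window center (inclusive boundary).
#' Projected mode uses Euclidean distance in metres; geographic mode uses
#' haversine distance (Earth radius 6371 km). Windows clipped by the
#' raster edge are returned with \code{truncated = TRUE}; a window whose
#' center falls outside the raster footprint is an error.
#'
#' @param raster an [ElevationRaster-class].
#' @param center numeric(2): x, y of the window center (same CRS as the
#'   raster).
#' @param radiusKm window radius in kilometres (> 0).
#' @param stride use every \code{stride}-th row and column of the grid
#'   (1 = every cell). An aggregation shortcut for very large windows;
#'   stride > 1 trades a small sampling error for speed.
#' @return list with \code{values} (numeric, possibly empty),
#'   \code{truncated} (logical: window clipped by the raster edge) and
#'   \code{nNodata} (count of in-circle nodata cells).
#' @seealso [sdElevation()]
#' @export
windowValues <- function(raster, center, radiusKm, stride = 1L) {
  stopifnot(methods::is(raster, "ElevationRaster"))
  if (!is.finite(radiusKm) || radiusKm <= 0) stop("radiusKm must be > 0")
  stride <- max(1L, as.integer(stride))
  fp <- rasterFootprint(raster)
  cx <- center[1]; cy <- center[2]
  if (cx < fp["xmin"] || cx > fp["xmax"] || cy < fp["ymin"] || cy > fp["ymax"])
    stop("window center lies outside the raster footprint")

  geographic <- crsMode(raster) == "geographic"
  radiusM <- radiusKm * 1000
  xs <- cellCenterX(raster)
  ys <- cellCenterY(raster)

  if (geographic) {
    # conservative bounding box in degrees, then exact haversine mask
    dlat <- radiusM / 111194.9
    dlon <- radiusM / (111194.9 * max(cos(cy * pi / 180), 1e-6))
    jset <- which(xs >= cx - dlon & xs <= cx + dlon)
    iset <- which(ys >= cy - dlat & ys <= cy + dlat)
  } else {
    jset <- which(xs >= cx - radiusM & xs <= cx + radiusM)
    iset <- which(ys >= cy - radiusM & ys <= cy + radiusM)
  }
  # truncation: does the circle extend past the grid edge?
  truncated <- if (geographic) {
    (cx - dlon < fp["xmin"]) || (cx + dlon > fp["xmax"]) ||
      (cy - dlat < fp["ymin"]) || (cy + dlat > fp["ymax"])
  } else {
    (cx - radiusM < fp["xmin"]) || (cx + radiusM > fp["xmax"]) ||
      (cy - radiusM < fp["ymin"]) || (cy + radiusM > fp["ymax"])
  }
  iset <- iset[seq(1L, length(iset), by = stride)]
  jset <- jset[seq(1L, length(jset), by = stride)]
  if (!length(iset) || !length(jset))
    return(list(values = numeric(0), truncated = truncated, nNodata = 0L))

  sub <- raster@values[iset, jset, drop = FALSE]
  if (geographic) {
    grid <- cbind(rep(xs[jset], each = length(iset)),
                  rep(ys[iset], times = length(jset)))
    d <- geosphere::distHaversine(c(cx, cy), grid, r = 6371000)
    inw <- matrix(d <= radiusM, nrow = length(iset))
  } else {
    dx2 <- (xs[jset] - cx)^2
    dy2 <- (ys[iset] - cy)^2
    inw <- outer(dy2, dx2, "+") <= radiusM^2
  }
  vals <- sub[inw]
  nNodata <- sum(is.na(vals))
  list(values = vals[!is.na(vals)], truncated = truncated,
       nNodata = as.integer(nNodata))
}

#' Standard deviation of elevation
#'
#' Sample standard deviation (denominator n - 1) of a window's elevation
#' values — the geodiversity measure of the analysis. Fewer than two
#' values give \code{NA} (flagged missing, never an error), so degenerate
#' windows propagate as missing rows rather than stopping a run.
#'
#' @param values numeric vector of elevations in metres.
#' @return SD in metres, or \code{NA_real_} when fewer than 2 values.
#' @examples
#' sdElevation(c(0, 2))      # sqrt(2)
#' sdElevation(c(1, 2, 3, 4))
#' @export
sdElevation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) return(NA_real_)
  stats::sd(values)
}
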