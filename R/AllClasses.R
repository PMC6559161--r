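#' @include AllGenerics.R
NULL

#' Georeferenced elevation grid
#'
#' An \code{ElevationRaster} holds a single-band elevation grid together
#' with the minimal georeferencing the pipeline needs: the coordinate of
#' the upper-left corner of the grid, a square cell size, a nodata
#' sentinel, and the coordinate mode. Values are stored row-major with
#' row 1 the northernmost row, and every cell value is addressed at its
#' cell center; nodata cells are held as \code{NA} internally.
#'
#' In \code{"projected"} mode coordinates and cell size are metres; in
#' \code{"geographic"} mode coordinates are degrees longitude/latitude,
#' cell size is degrees, and all distances are great-circle (haversine,
#' Earth radius 6371 km).
#'
#' @slot values numeric matrix (ny rows x nx columns), \code{NA} = nodata.
#' @slot origin numeric(2), x and y of the upper-left corner of the grid
#'   (not of the first cell center).
#' @slot cellSize positive scalar, cell edge length.
#' @slot nodata scalar used as the nodata sentinel on disk.
#' @slot crsMode \code{"projected"} or \code{"geographic"}.
#'
#' @seealso [generateElevationSurface()], [readElevationRaster()],
#'   [windowValues()]
#' @export
setClass("ElevationRaster",
  representation(
    values = "matrix",
    origin = "numeric",
    cellSize = "numeric",
    nodata = "numeric",
    crsMode = "character"
  ),
  prototype(
    origin = c(0, 0),
    cellSize = 1,
    nodata = -9999,
    crsMode = "projected"
  )
)

setValidity("ElevationRaster", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (nrow(v) < 2L || ncol(v) < 2L)
    msg <- c(msg, "raster must have at least 2 rows and 2 columns")
  if (length(object@origin) != 2L || anyNA(object@origin))
    msg <- c(msg, "origin must be a finite numeric of length 2")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a positive scalar")
  if (!object@crsMode %in% c("projected", "geographic"))
    msg <- c(msg, "crsMode must be 'projected' or 'geographic'")
  if (length(msg)) msg else TRUE
})

#' Plot communities with coordinates
#'
#' A \code{PlotCommunitySet} is the package's central community container:
#' a sparse species x plot basal-area matrix plus one planar or geographic
#' coordinate per plot. Basal areas are strictly positive where present
#' (m^2 summed over stems); absence is a structural zero. Every retained
#' plot holds at least one species.
#'
#' @slot abundance \code{dgCMatrix}, species (rows) x plots (columns),
#'   dimnames give species codes and plot ids.
#' @slot coords numeric matrix, one row per plot, columns \code{x},
#'   \code{y}, in the same order as the abundance columns.
#' @slot crsMode \code{"projected"} (metres) or \code{"geographic"}
#'   (degrees lon/lat).
#'
#' @seealso [readPlotTable()], [generatePlotNetwork()],
#'   [neighborhoodMembers()]
#' @export
setClass("PlotCommunitySet",
  representation(
    abundance = "dgCMatrix",
    coords = "matrix",
    crsMode = "character"
  ),
  prototype(crsMode = "projected")
)

setValidity("PlotCommunitySet", function(object) {
  msg <- character()
  a <- object@abundance
  if (is.null(colnames(a)) || anyDuplicated(colnames(a)))
    msg <- c(msg, "plot ids (column names) must be present and unique")
  if (is.null(rownames(a)) || anyDuplicated(rownames(a)))
    msg <- c(msg, "species codes (row names) must be present and unique")
  if (length(a@x) && any(a@x <= 0))
    msg <- c(msg, "all stored basal areas must be strictly positive")
  if (ncol(a) > 0 && any(Matrix::colSums(a) <= 0))
    msg <- c(msg, "every plot must contain at least one species")
  if (!is.numeric(object@coords) || ncol(object@coords) != 2L ||
      nrow(object@coords) != ncol(a))
    msg <- c(msg, "coords must be a numeric matrix with one (x, y) row per plot")
  if (!object@crsMode %in% c("projected", "geographic"))
    msg <- c(msg, "crsMode must be 'projected' or 'geographic'")
  if (length(msg)) msg else TRUE
})

#' Fitted diversity-heterogeneity regression
#'
#' A \code{ModelFit} records one regression of a diversity response on the
#' standard deviation of elevation: a gamma GLM with log link
#' (\code{family = "gamma-log"}, auxiliary parameter = shape nu) or a
#' beta regression with logit link and constant precision
#' (\code{family = "beta-logit"}, auxiliary parameter = precision phi).
#' \code{trace} stores one value per iteration on a scale where larger is
#' better (profile criterion for the gamma IRLS, log-likelihood for the
#' beta Newton ascent), so likelihood ascent can be asserted.
#'
#' @slot family \code{"gamma-log"} or \code{"beta-logit"}.
#' @slot coefficients named numeric(2): intercept and slope on the link
#'   scale (slope per metre of elevation SD).
#' @slot aux gamma shape nu or beta precision phi (> 0 when converged).
#' @slot loglik maximized log-likelihood.
#' @slot converged logical convergence flag; non-converged fits are
#'   excluded from replicate summaries.
#' @slot n number of observations.
#' @slot trace per-iteration ascent criterion (see above).
#'
#' @seealso [fitGammaGLM()], [fitBetaRegression()], [standardizedSlope()]
#' @export
setClass("ModelFit",
  representation(
    family = "character",
    coefficients = "numeric",
    aux = "numeric",
    loglik = "numeric",
    converged = "logical",
    n = "integer",
    trace = "numeric"
  )
)

setValidity("ModelFit", function(object) {
  msg <- character()
  if (!object@family %in% c("gamma-log", "beta-logit"))
    msg <- c(msg, "family must be 'gamma-log' or 'beta-logit'")
  if (length(object@coefficients) != 2L)
    msg <- c(msg, "coefficients must have length 2 (intercept, slope)")
  if (isTRUE(object@converged) && (!is.finite(object@aux) || object@aux <= 0))
    msg <- c(msg, "aux must be positive for a converged fit")
  if (length(msg)) msg else TRUE
})
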