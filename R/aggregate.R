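#' @include plot-communities.R geodiversity.R diversity.R subsample.R
NULL

# distance (km) from a point to the boundary of a polygon ring, by
# point-to-segment distances; geographic mode densifies each segment and
# uses haversine distances (an approximation adequate for a coarse edge
# buffer)
distanceToRingKm <- function(p, ring, crsMode, densify = 20L) {
  segA <- ring[seq_len(nrow(ring) - 1L), , drop = FALSE]
  segB <- ring[-1L, , drop = FALSE]
  if (!all(ring[1, ] == ring[nrow(ring), ])) {  # close the ring
    segA <- rbind(segA, ring[nrow(ring), ])
    segB <- rbind(segB, ring[1, ])
  }
  if (crsMode == "projected") {
    dx <- segB[, 1] - segA[, 1]
    dy <- segB[, 2] - segA[, 2]
    len2 <- dx^2 + dy^2
    t <- ((p[1] - segA[, 1]) * dx + (p[2] - segA[, 2]) * dy) /
      ifelse(len2 > 0, len2, 1)
    t <- pmin(1, pmax(0, t))
    qx <- segA[, 1] + t * dx
    qy <- segA[, 2] + t * dy
    min(sqrt((p[1] - qx)^2 + (p[2] - qy)^2)) / 1000
  } else {
    ts <- seq(0, 1, length.out = densify)
    pts <- do.call(rbind, lapply(seq_len(nrow(segA)), function(k)
      cbind(segA[k, 1] + ts * (segB[k, 1] - segA[k, 1]),
            segA[k, 2] + ts * (segB[k, 2] - segA[k, 2]))))
    min(geosphere::distHaversine(p, pts, r = 6371000)) / 1000
  }
}

#' Drop plots near the study-region border
#'
#' Retains plots that lie inside the region boundary at a distance of at
#' least \code{bufferKm} from it, discarding border plots to avoid edge
#' effects (neighbourhoods of border plots would be clipped by the region
#' itself).
#'
#' @param plots a [PlotCommunitySet-class].
#' @param boundary region boundary: a two-column vertex matrix, a list of
#'   such matrices (multiple outer rings), or numeric(4)
#'   \code{c(xmin, xmax, ymin, ymax)} for a rectangle.
#' @param bufferKm buffer distance in km (>= 0; 0 retains all plots
#'   inside the boundary).
#' @return A [PlotCommunitySet-class] of retained plots. The count of
#'   dropped plots is reported with a message and recoverable as
#'   \code{nPlots(plots) - nPlots(result)}.
#' @export
filterEdgePlots <- function(plots, boundary, bufferKm = 100) {
  stopifnot(methods::is(plots, "PlotCommunitySet"))
  if (bufferKm < 0) stop("bufferKm must be >= 0")
  rings <- if (is.list(boundary)) boundary
  else if (is.matrix(boundary)) list(boundary)
  else if (is.numeric(boundary) && length(boundary) == 4L) {
    b <- boundary
    list(cbind(x = c(b[1], b[2], b[2], b[1], b[1]),
               y = c(b[3], b[3], b[4], b[4], b[3])))
  } else stop("boundary must be a ring matrix, list of rings, or c(xmin, xmax, ymin, ymax)")

  coords <- plotCoords(plots)
  if (is.numeric(boundary) && !is.list(boundary) && !is.matrix(boundary)) {
    # rectangle: inclusive comparison is exact and robust to degenerate
    # (zero-height or zero-width) extents
    b <- boundary
    inside <- coords[, 1] >= b[1] & coords[, 1] <= b[2] &
      coords[, 2] >= b[3] & coords[, 2] <= b[4]
  } else {
    inside <- rep(FALSE, nrow(coords))
    for (ring in rings) {
      ringOpen <- if (all(ring[1, ] == ring[nrow(ring), ]))
        ring[-nrow(ring), , drop = FALSE] else ring
      inside <- inside | mgcv::in.out(rbind(ringOpen, ringOpen[1, ]), coords)
    }
  }
  if (bufferKm > 0) {
    far <- vapply(seq_len(nrow(coords)), function(i) {
      if (!inside[i]) return(FALSE)
      min(vapply(rings, function(r)
        distanceToRingKm(coords[i, ], r, plots@crsMode), numeric(1))) >=
        bufferKm
    }, logical(1))
  } else far <- inside
  if (!any(far))
    stop("no plots remain after the ", bufferKm,
         " km edge filter; use a smaller buffer or a larger region")
  nDropped <- sum(!far)
  if (nDropped > 0)
    message("filterEdgePlots: dropped ", nDropped, " of ", length(far),
            " plots within ", bufferKm, " km of the region border")
  plots[which(far)]
}

#' Plots within a radius of a focal plot
#'
#' All plots at distance <= \code{radiusKm} from the focal plot
#' (inclusive boundary), the focal plot always included.
#'
#' @param plots a [PlotCommunitySet-class].
#' @param focalId plot id of the focal plot (must be present).
#' @param radiusKm neighbourhood radius in km (0 gives the focal plot
#'   alone).
#' @return A [PlotCommunitySet-class] of member plots.
#' @export
neighborhoodMembers <- function(plots, focalId, radiusKm) {
  stopifnot(methods::is(plots, "PlotCommunitySet"))
  k <- match(focalId, plotIds(plots))
  if (is.na(k)) stop("focal plot ", focalId, " not found")
  d <- distanceToManyKm(plotCoords(plots)[k, ], plotCoords(plots),
                        plots@crsMode)
  members <- which(d <= radiusKm | seq_along(d) == k)
  plots[members]
}

#' Build the per-plot, per-radius diversity-geodiversity table
#'
#' For every focal plot and every radius: alpha, beta and gamma diversity
#' of the circular plot neighbourhood, and the SD of elevation of all
#' raster cells in the co-centred circular window. Missing values (beta
#' of single-plot neighbourhoods; SD of windows with fewer than two
#' cells) are propagated as \code{NA} with flags, never dropped. All
#' radii for one focal plot are computed in one pass over its sorted
#' neighbour distances; results are identical to a naive per-radius
#' search.
#'
#' @param plots a [PlotCommunitySet-class], already edge-filtered.
#' @param raster an [ElevationRaster-class] in the same CRS.
#' @param radiiKm positive, sorted neighbourhood radii in km.
#' @param stride raster sampling stride for [windowValues()].
#' @param proportions Bray-Curtis variant switch, see
#'   [pairwiseDissimilarity()].
#' @return data.frame with columns \code{plot_id, radius_km, alpha, beta,
#'   gamma, sd_elev, n_plots_in_radius, truncated_window}; exactly
#'   \code{nPlots(plots) * length(radiiKm)} rows.
#' @export
buildScaleTable <- function(plots, raster, radiiKm, stride = 1L,
                            proportions = FALSE) {
  stopifnot(methods::is(plots, "PlotCommunitySet"),
            methods::is(raster, "ElevationRaster"))
  if (plots@crsMode != crsMode(raster))
    stop("plots and raster disagree on CRS mode (",
         plots@crsMode, " vs ", crsMode(raster), ")")
  radiiKm <- as.numeric(radiiKm)
  if (any(radiiKm <= 0) || is.unsorted(radiiKm))
    stop("radiiKm must be positive and sorted increasing")
  n <- nPlots(plots)
  ids <- plotIds(plots)
  coords <- plotCoords(plots)
  perPlotD <- plotEffectiveSpeciesNumbers(abundanceMatrix(plots))

  rows <- vector("list", n * length(radiiKm))
  r <- 0L
  for (i in seq_len(n)) {
    d <- distanceToManyKm(coords[i, ], coords, plots@crsMode)
    ord <- order(d)
    for (rk in radiiKm) {
      members <- ord[seq_len(findInterval(rk, d[ord]))]
      if (!i %in% members) members <- c(i, members)
      sub <- plots[members]
      w <- windowValues(raster, coords[i, ], rk, stride = stride)
      r <- r + 1L
      rows[[r]] <- data.frame(
        plot_id = ids[i], radius_km = rk,
        alpha = stats::median(perPlotD[members]),
        beta = betaDiversity(sub, proportions = proportions),
        gamma = gammaDiversity(sub),
        sd_elev = sdElevation(w$values),
        n_plots_in_radius = length(members),
        truncated_window = w$truncated,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
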