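#' @include plot-communities.R
NULL

#' Read a long-format plot table
#'
#' Expects a CSV with header columns \code{plot_id, x, y, species,
#' basal_area} — one row per plot x species, the long format forest
#' inventory exports use. Rows are grouped by \code{plot_id}; duplicate
#' (plot, species) rows are summed (subplot stems aggregate to plot
#' totals); zero or negative basal areas are rejected with the offending
#' file row number.
#'
#' @param path CSV path.
#' @param crsMode coordinate mode of the x/y columns.
#' @return A [PlotCommunitySet-class].
#' @seealso [writePlotTable()]
#' @export
readPlotTable <- function(path, crsMode = c("projected", "geographic")) {
  crsMode <- match.arg(crsMode)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("plot_id", "x", "y", "species", "basal_area")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("plot table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("plot table has no data rows")
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad))
      stop("non-numeric ", col, " in plot table at file row ",
           bad[1] + 1L)  # +1 for the header line
    v
  }
  ba <- num("basal_area")
  xs <- num("x"); ys <- num("y")
  badBa <- which(!is.finite(ba) | ba <= 0)
  if (length(badBa))
    stop("basal_area must be > 0; offending file row ", badBa[1] + 1L)

  pid <- factor(df$plot_id, levels = unique(df$plot_id))
  sp <- factor(df$species, levels = sort(unique(df$species)))
  # sparseMatrix sums duplicated (species, plot) entries
  a <- Matrix::sparseMatrix(
    i = as.integer(sp), j = as.integer(pid), x = ba,
    dims = c(nlevels(sp), nlevels(pid)),
    dimnames = list(levels(sp), levels(pid)))
  first <- !duplicated(pid)
  coords <- cbind(x = xs[first], y = ys[first])
  PlotCommunitySet(a, coords, crsMode = crsMode)
}

#' Write a plot table in the long CSV dialect
#'
#' @param x a [PlotCommunitySet-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writePlotTable <- function(x, path) {
  a <- abundanceMatrix(x)
  tr <- Matrix::summary(a)
  ord <- order(tr$j, tr$i)
  df <- data.frame(
    plot_id = colnames(a)[tr$j[ord]],
    x = plotCoords(x)[tr$j[ord], "x"],
    y = plotCoords(x)[tr$j[ord], "y"],
    species = rownames(a)[tr$i[ord]],
    basal_area = tr$x[ord])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a region boundary polygon from GeoJSON
#'
#' Accepts a GeoJSON \code{Polygon}, \code{MultiPolygon}, \code{Feature}
#' or \code{FeatureCollection}; only outer rings are used (holes in a
#' study region are not modelled). Returns a list of two-column vertex
#' matrices.
#'
#' @param path GeoJSON file path.
#' @return list of numeric matrices (columns x, y), one per outer ring.
#' @export
readRegionBoundary <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  geoms <- switch(g$type %||% "",
    "FeatureCollection" = lapply(g$features, `[[`, "geometry"),
    "Feature" = list(g$geometry),
    "Polygon" = , "MultiPolygon" = list(g),
    stop("unsupported GeoJSON type: ", g$type))
  rings <- list()
  for (gm in geoms) {
    ringToM <- function(ring)
      do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (gm$type == "Polygon") {
      rings <- c(rings, list(ringToM(gm$coordinates[[1]])))
    } else if (gm$type == "MultiPolygon") {
      rings <- c(rings, lapply(gm$coordinates, function(poly)
        ringToM(poly[[1]])))
    } else stop("unsupported geometry type: ", gm$type)
  }
  lapply(rings, function(m) {
    colnames(m) <- c("x", "y")
    m
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write pipeline result tables
#'
#' Writes two CSVs into \code{outDir}: \code{scale_table.csv} (one row
#' per focal plot x radius: plot_id, radius_km, alpha, beta, gamma,
#' sd_elev, n_plots_in_radius) and \code{scaling_summaries.csv} (one row
#' per radius x diversity form: radius_km, form, slope percentiles,
#' median pseudo-R^2, replicate count). Missing values are written as
#' empty fields; numeric precision is full double precision, so a
#' write/read round trip preserves at least 10 significant digits.
#'
#' @param scaleTable data.frame from [buildScaleTable()].
#' @param summaries list of summaries from [summarizeReplicates()] (or a
#'   pre-flattened data.frame); may be empty, giving a header-only file.
#' @param outDir output directory, created if needed.
#' @return character(2) of file paths, invisibly.
#' @export
writeResults <- function(scaleTable, summaries, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  stPath <- file.path(outDir, "scale_table.csv")
  smPath <- file.path(outDir, "scaling_summaries.csv")
  stCols <- c("plot_id", "radius_km", "alpha", "beta", "gamma",
              "sd_elev", "n_plots_in_radius")
  st <- as.data.frame(scaleTable)[, stCols, drop = FALSE]
  utils::write.csv(format(st, digits = 15, trim = TRUE, scientific = FALSE),
                   stPath, row.names = FALSE, quote = FALSE, na = "")
  sm <- summariesToDataFrame(summaries)
  utils::write.csv(format(sm, digits = 15, trim = TRUE, scientific = FALSE),
                   smPath, row.names = FALSE, quote = FALSE, na = "")
  invisible(c(scale_table = stPath, scaling_summaries = smPath))
}

#' Flatten replicate summaries to the output schema
#'
#' @param summaries list of [summarizeReplicates()] results, or an
#'   already-flat data.frame.
#' @return data.frame with columns radius_km, form, slope_p2.5,
#'   slope_p25, slope_p50, slope_p75, slope_p97.5, median_pseudo_r2,
#'   n_replicates.
#' @export
summariesToDataFrame <- function(summaries) {
  cols <- c("radius_km", "form", "slope_p2.5", "slope_p25", "slope_p50",
            "slope_p75", "slope_p97.5", "median_pseudo_r2", "n_replicates")
  if (is.data.frame(summaries)) {
    stopifnot(all(cols %in% names(summaries)))
    return(summaries[, cols, drop = FALSE])
  }
  if (!length(summaries)) {
    out <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(cols)), cols))
    out$form <- character(0)
    return(out[, cols])
  }
  do.call(rbind, lapply(summaries, function(s) {
    p <- s$slopePercentiles
    data.frame(
      radius_km = s$radiusKm, form = s$form,
      `slope_p2.5` = p[["2.5%"]], slope_p25 = p[["25%"]],
      slope_p50 = p[["50%"]], slope_p75 = p[["75%"]],
      `slope_p97.5` = p[["97.5%"]],
      median_pseudo_r2 = s$medianPseudoR2,
      n_replicates = s$nReplicatesUsed,
      check.names = FALSE, stringsAsFactors = FALSE)
  }))
}
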