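#' @include elevation-raster.R
NULL

# ---- ESRI ASCII grid ------------------------------------------------------

readAsciiGrid <- function(path, crsMode = "projected") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^[a-zA-Z]", trimws(lines[i]))) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(parts) != 2L)
      stop("malformed ESRI ASCII header line: ", lines[i])
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("ESRI ASCII header is missing: ", paste(miss, collapse = ", "))
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  rows <- lines[i:length(lines)]
  if (length(rows) != nr)
    stop("ESRI ASCII grid has ", length(rows), " data rows, expected ", nr)
  vals <- lapply(seq_along(rows), function(k) {
    v <- suppressWarnings(
      as.numeric(strsplit(trimws(rows[k]), "[[:space:]]+")[[1]]))
    if (length(v) != nc)
      stop("row ", k, " of ESRI ASCII grid has ", length(v),
           " values, expected ", nc)
    if (anyNA(v))
      stop("non-numeric value in row ", k, " of ESRI ASCII grid")
    v
  })
  m <- do.call(rbind, vals)
  # header gives the lower-left corner; convert to upper-left origin
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else
    if (!is.null(hdr$xllcenter)) hdr$xllcenter - hdr$cellsize / 2 else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else
    if (!is.null(hdr$yllcenter)) hdr$yllcenter - hdr$cellsize / 2 else 0
  ElevationRaster(m, origin = c(xll, yll + nr * hdr$cellsize),
                  cellSize = hdr$cellsize, nodata = nodata,
                  crsMode = crsMode)
}

writeAsciiGrid <- function(raster, path) {
  m <- raster@values
  m[is.na(m)] <- raster@nodata
  fp <- rasterFootprint(raster)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", format(fp["xmin"], digits = 15)),
    paste("yllcorner", format(fp["ymin"], digits = 15)),
    paste("cellsize", format(raster@cellSize, digits = 15)),
    paste("NODATA_value", format(raster@nodata, digits = 15))
  ), con)
  writeLines(apply(m, 1L, function(r)
    paste(format(r, digits = 10, trim = TRUE, scientific = FALSE),
          collapse = " ")), con)
  invisible(path)
}

# ---- minimal GeoTIFF codec ------------------------------------------------
# Single band, uncompressed, striped; float32/float64 and common integer
# sample formats on read, float32 on write. Georeferencing through the
# ModelPixelScale + ModelTiepoint tags and nodata through GDAL's ASCII
# nodata tag. (No installed R package reads float GeoTIFFs, hence this
# small codec; it is not a general TIFF implementation.)

tiffTypeSize <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `6` = 1L,
                  `8` = 2L, `9` = 4L, `11` = 4L, `12` = 8L)

readTiffValue <- function(con, entry, endian) {
  type <- entry$type; count <- entry$count
  size <- tiffTypeSize[as.character(type)]
  if (is.na(size)) return(NULL)
  total <- size * count
  if (total > 4) {
    seek(con, entry$valueOffset)
  } else {
    seek(con, entry$inlinePos)
  }
  switch(as.character(type),
    `1` = readBin(con, "integer", count, size = 1, signed = FALSE, endian = endian),
    `2` = {
      r <- readBin(con, "raw", count)
      rawToChar(r[r != as.raw(0L)])  # strip NUL terminators
    },
    `3` = readBin(con, "integer", count, size = 2, signed = FALSE, endian = endian),
    `4` = {
      v <- readBin(con, "integer", count, size = 4, endian = endian)
      ifelse(v < 0, v + 2^32, v)  # LONG is unsigned
    },
    `6` = readBin(con, "integer", count, size = 1, signed = TRUE, endian = endian),
    `8` = readBin(con, "integer", count, size = 2, signed = TRUE, endian = endian),
    `9` = readBin(con, "integer", count, size = 4, endian = endian),
    `11` = readBin(con, "double", count, size = 4, endian = endian),
    `12` = readBin(con, "double", count, size = 8, endian = endian),
    NULL)
}

readGeoTiff <- function(path, crsMode = "projected") {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  endian <- if (identical(as.integer(magic), c(73L, 73L))) "little"
  else if (identical(as.integer(magic), c(77L, 77L))) "big"
  else stop("not a TIFF file: ", path)
  fortytwo <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
  if (fortytwo != 42L) stop("not a TIFF file: ", path)
  ifdOffset <- readBin(con, "integer", 1, size = 4, endian = endian)
  seek(con, ifdOffset)
  nEntries <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
  entries <- vector("list", nEntries)
  for (k in seq_len(nEntries)) {
    pos <- ifdOffset + 2 + (k - 1) * 12
    seek(con, pos)
    tag <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
    type <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
    count <- readBin(con, "integer", 1, size = 4, endian = endian)
    valueOffset <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (valueOffset < 0) valueOffset <- valueOffset + 2^32
    entries[[k]] <- list(tag = tag, type = type, count = count,
                         valueOffset = valueOffset, inlinePos = pos + 8)
  }
  tagValue <- function(tag, default = NULL) {
    for (e in entries) if (e$tag == tag) return(readTiffValue(con, e, endian))
    default
  }
  nx <- tagValue(256); ny <- tagValue(257)
  if (is.null(nx) || is.null(ny)) stop("TIFF lacks image dimensions")
  bits <- tagValue(258, 1)
  compression <- tagValue(259, 1)
  if (compression != 1) stop("only uncompressed TIFF is supported")
  spp <- tagValue(277, 1)
  if (spp != 1) stop("only single-band rasters are supported")
  stripOffsets <- tagValue(273)
  rowsPerStrip <- tagValue(278, ny)
  byteCounts <- tagValue(279)
  sampleFormat <- tagValue(339, 1)
  if (is.null(stripOffsets)) stop("TIFF lacks strip offsets")
  bytesPer <- bits[1] / 8
  what <- if (sampleFormat[1] == 3) "double" else "integer"
  signed <- sampleFormat[1] != 1
  vals <- numeric(0)
  for (s in seq_along(stripOffsets)) {
    seek(con, stripOffsets[s])
    nv <- if (!is.null(byteCounts)) byteCounts[s] / bytesPer else nx * rowsPerStrip
    v <- readBin(con, what, n = nv, size = bytesPer,
                 signed = if (what == "integer" && bytesPer < 4) signed else TRUE,
                 endian = endian)
    vals <- c(vals, as.numeric(v))
  }
  if (length(vals) != nx * ny)
    stop("TIFF strip data is inconsistent with image dimensions")
  m <- matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)
  scaleTag <- tagValue(33550)
  tiepoint <- tagValue(33922)
  cellSize <- if (!is.null(scaleTag)) scaleTag[1] else 1
  origin <- if (!is.null(tiepoint)) {
    # model coordinates of raster point (i, j): shift back to UL corner
    c(tiepoint[4] - tiepoint[1] * cellSize,
      tiepoint[5] + tiepoint[2] * cellSize)
  } else c(0, ny * cellSize)
  nodataStr <- tagValue(42113)
  nodata <- if (!is.null(nodataStr))
    suppressWarnings(as.numeric(trimws(nodataStr))) else -9999
  if (is.na(nodata)) nodata <- -9999
  ElevationRaster(m, origin = origin, cellSize = cellSize, nodata = nodata,
                  crsMode = crsMode)
}

writeGeoTiff <- function(raster, path) {
  m <- raster@values
  m[is.na(m)] <- raster@nodata
  ny <- nrow(m); nx <- ncol(m)
  dataBytes <- 4L * nx * ny
  dataOffset <- 8L
  ifdOffset <- dataOffset + dataBytes
  if (ifdOffset %% 2L == 1L) ifdOffset <- ifdOffset + 1L
  # GDAL_NODATA is a NUL-terminated ASCII tag
  nodataRaw <- c(charToRaw(format(raster@nodata, digits = 15)), as.raw(0L))
  tags <- list(
    list(256, 4L, 1L, nx),
    list(257, 4L, 1L, ny),
    list(258, 3L, 1L, 32L),
    list(259, 3L, 1L, 1L),
    list(262, 3L, 1L, 1L),
    list(273, 4L, 1L, dataOffset),
    list(277, 3L, 1L, 1L),
    list(278, 4L, 1L, ny),
    list(279, 4L, 1L, dataBytes),
    list(339, 3L, 1L, 3L),
    list(33550, 12L, 3L, NA),   # ModelPixelScale -> external
    list(33922, 12L, 6L, NA),   # ModelTiepoint  -> external
    list(42113, 2L, length(nodataRaw), NA)
  )
  nTags <- length(tags)
  ifdBytes <- 2L + nTags * 12L + 4L
  extOffset <- ifdOffset + ifdBytes
  scaleOffset <- extOffset
  tieOffset <- scaleOffset + 24L
  nodataOffset <- tieOffset + 48L

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifdOffset), con, size = 4, endian = "little")
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  if ((dataOffset + dataBytes) %% 2L == 1L) writeBin(as.raw(0L), con)

  writeBin(as.integer(nTags), con, size = 2, endian = "little")
  for (tg in tags) {
    writeBin(as.integer(tg[[1]]), con, size = 2, endian = "little")
    writeBin(as.integer(tg[[2]]), con, size = 2, endian = "little")
    writeBin(as.integer(tg[[3]]), con, size = 4, endian = "little")
    value <- switch(as.character(tg[[1]]),
      `33550` = scaleOffset, `33922` = tieOffset, `42113` = nodataOffset,
      tg[[4]])
    if (tg[[2]] == 3L) {  # SHORT values are left-justified in the 4 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  writeBin(as.numeric(c(raster@cellSize, raster@cellSize, 0)), con,
           size = 8, endian = "little")
  writeBin(as.numeric(c(0, 0, 0, raster@origin[1], raster@origin[2], 0)),
           con, size = 8, endian = "little")
  writeBin(nodataRaw, con)
  invisible(path)
}

# ---- public interface -----------------------------------------------------

#' Read an elevation raster (GeoTIFF or ESRI ASCII grid)
#'
#' The format is detected from the file's magic bytes (TIFF) with ESRI
#' ASCII grid as the fallback. Values arrive row-major with row 1 the
#' northernmost row; nodata cells become \code{NA} and are excluded from
#' all downstream statistics.
#'
#' @param path file path.
#' @param crsMode coordinate mode of the file's coordinates.
#' @return An [ElevationRaster-class].
#' @seealso [writeElevationRaster()]
#' @export
readElevationRaster <- function(path, crsMode = c("projected", "geographic")) {
  crsMode <- match.arg(crsMode)
  if (!file.exists(path)) stop("no such raster file: ", path)
  magic <- readBin(path, "raw", 4)
  isTiff <- length(magic) == 4 &&
    (identical(as.integer(magic[1:2]), c(73L, 73L)) ||
       identical(as.integer(magic[1:2]), c(77L, 77L)))
  if (isTiff) readGeoTiff(path, crsMode) else readAsciiGrid(path, crsMode)
}

#' Write an elevation raster
#'
#' @param raster an [ElevationRaster-class].
#' @param path output path; format chosen by extension (\code{.tif} /
#'   \code{.tiff} for GeoTIFF, anything else ESRI ASCII grid) unless
#'   \code{format} is given.
#' @param format \code{"auto"}, \code{"ascii"} or \code{"geotiff"}.
#'   GeoTIFF output stores float32 samples, so values are rounded to
#'   single precision; the ASCII writer keeps 10 significant digits.
#' @return the path, invisibly.
#' @export
writeElevationRaster <- function(raster, path,
                                 format = c("auto", "ascii", "geotiff")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
      "geotiff" else "ascii"
  if (format == "geotiff") writeGeoTiff(raster, path)
  else writeAsciiGrid(raster, path)
}
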