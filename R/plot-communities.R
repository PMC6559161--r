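#' @include AllClasses.R
NULL

#' Construct a PlotCommunitySet
#'
#' @param abundance species x plot matrix (dense or sparse) of strictly
#'   positive basal areas; zeros are dropped. Dimnames are required.
#' @param coords numeric matrix or data.frame with columns \code{x},
#'   \code{y}, one row per plot (same order as abundance columns).
#' @param crsMode \code{"projected"} (metres) or \code{"geographic"}
#'   (degrees lon/lat).
#' @return A [PlotCommunitySet-class].
#' @examples
#' a <- matrix(c(1, 0, 2, 3), 2, 2,
#'             dimnames = list(c("ABCO", "PIPO"), c("p1", "p2")))
#' pcs <- PlotCommunitySet(a, cbind(x = c(0, 1000), y = c(0, 0)))
#' nPlots(pcs)
#' @export
PlotCommunitySet <- function(abundance, coords,
                             crsMode = c("projected", "geographic")) {
  crsMode <- match.arg(crsMode)
  a <- methods::as(methods::as(methods::as(
    Matrix::Matrix(abundance, sparse = TRUE), "dMatrix"),
    "generalMatrix"), "CsparseMatrix")
  a <- Matrix::drop0(a)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y")
  rownames(coords) <- colnames(a)
  methods::new("PlotCommunitySet", abundance = a, coords = coords,
               crsMode = crsMode)
}

#' @describeIn PlotCommunitySet Sparse species x plot basal-area matrix.
#' @param x a \code{PlotCommunitySet}.
#' @export
setMethod("abundanceMatrix", "PlotCommunitySet", function(x) x@abundance)

#' @describeIn PlotCommunitySet Plot coordinate matrix (x, y).
#' @export
setMethod("plotCoords", "PlotCommunitySet", function(x) x@coords)

#' @describeIn PlotCommunitySet Plot identifiers.
#' @export
setMethod("plotIds", "PlotCommunitySet", function(x) colnames(x@abundance))

#' @describeIn PlotCommunitySet Species codes.
#' @export
setMethod("speciesIds", "PlotCommunitySet", function(x) rownames(x@abundance))

#' @describeIn PlotCommunitySet Number of plots.
#' @export
setMethod("nPlots", "PlotCommunitySet", function(x) ncol(x@abundance))

#' @describeIn PlotCommunitySet Coordinate mode.
#' @export
setMethod("crsMode", "PlotCommunitySet", function(x) x@crsMode)

#' Subset plots
#'
#' \code{x[i]} keeps the plots selected by \code{i} (ids, indices or a
#' logical vector); species with no occurrence in the kept plots are
#' retained as empty rows so species indexing stays stable.
#'
#' @param x a \code{PlotCommunitySet}.
#' @param i plot selector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "PlotCommunitySet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, colnames(x@abundance))
  if (anyNA(i)) stop("unknown plot id in subset")
  methods::new("PlotCommunitySet",
               abundance = x@abundance[, i, drop = FALSE],
               coords = x@coords[i, , drop = FALSE],
               crsMode = x@crsMode)
})

setMethod("show", "PlotCommunitySet", function(object) {
  a <- object@abundance
  cat("PlotCommunitySet:", ncol(a), "plots,", nrow(a), "species (",
      object@crsMode, ")\n")
  if (ncol(a)) {
    rich <- Matrix::colSums(a > 0)
    cat(sprintf("  per-plot richness: %d .. %d (median %g)\n",
                min(rich), max(rich), stats::median(rich)))
    cat(sprintf("  total basal area: %.3f m^2\n", sum(a@x)))
  }
})
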