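#' @include plot-communities.R seeds.R
NULL

#' Distance between two points in kilometres
#'
#' Euclidean distance / 1000 in projected mode (coordinates in metres);
#' haversine great-circle distance with Earth radius 6371 km in
#' geographic mode (coordinates in degrees lon/lat).
#'
#' @param p1,p2 numeric(2) coordinates.
#' @param crsMode \code{"projected"} or \code{"geographic"}.
#' @return distance in km.
#' @examples
#' pairwiseDistanceKm(c(0, 0), c(3000, 4000))            # 5
#' pairwiseDistanceKm(c(0, 0), c(1, 0), "geographic")    # 111.19...
#' @export
pairwiseDistanceKm <- function(p1, p2, crsMode = c("projected", "geographic")) {
  crsMode <- match.arg(crsMode)
  if (crsMode == "projected") {
    sqrt(sum((as.numeric(p1) - as.numeric(p2))^2)) / 1000
  } else {
    geosphere::distHaversine(as.numeric(p1), as.numeric(p2), r = 6371000) / 1000
  }
}

# km distances from one point to many (rows of `coords`)
distanceToManyKm <- function(p, coords, crsMode) {
  if (crsMode == "projected") {
    sqrt((coords[, 1] - p[1])^2 + (coords[, 2] - p[2])^2) / 1000
  } else {
    geosphere::distHaversine(as.numeric(p), coords, r = 6371000) / 1000
  }
}

#' Draw one spatially separated subsample of plots
#'
#' Seeded random-order greedy packing: plots are scanned in a uniformly
#' shuffled order and each plot is accepted if it lies at least
#' \code{minSeparationKm} from every previously accepted plot. Every
#' accepted pair therefore satisfies the separation, and the result is
#' maximal for the scanned order — no rejected plot could be appended.
#' The scan-order randomness is exactly the replicate-to-replicate
#' randomness the percentile confidence intervals consume.
#'
#' @param plots a [PlotCommunitySet-class].
#' @param minSeparationKm minimum pairwise separation in km (0 accepts
#'   every plot).
#' @param seed integer seed; identical inputs give identical subsamples.
#' @return An object of class \code{"SubsampleReplicate"}: a list with
#'   \code{plotIds} (in acceptance order), \code{seed},
#'   \code{minSeparationKm} and \code{replicateIndex} (NA unless drawn
#'   via [replicateSubsamples()]).
#' @export
drawSubsample <- function(plots, minSeparationKm, seed) {
  stopifnot(methods::is(plots, "PlotCommunitySet"))
  n <- nPlots(plots)
  if (n < 1L) stop("at least one plot is required")
  ids <- plotIds(plots)
  coords <- plotCoords(plots)
  ord <- withSeed(seed, sample.int(n))
  if (minSeparationKm <= 0) {
    acc <- ord
  } else {
    acc <- integer(0)
    for (k in ord) {
      if (!length(acc) ||
          all(distanceToManyKm(coords[k, ], coords[acc, , drop = FALSE],
                               plots@crsMode) >= minSeparationKm))
        acc <- c(acc, k)
    }
  }
  structure(list(plotIds = ids[acc], seed = as.integer(seed),
                 minSeparationKm = minSeparationKm,
                 replicateIndex = NA_integer_),
            class = "SubsampleReplicate")
}

#' @exportS3Method base::print
print.SubsampleReplicate <- function(x, ...) {
  cat("SubsampleReplicate:", length(x$plotIds), "plots, separation >=",
      x$minSeparationKm, "km, seed", x$seed,
      if (!is.na(x$replicateIndex)) paste0("(replicate ", x$replicateIndex, ")")
      else "", "\n")
  invisible(x)
}

#' Draw many independent subsample replicates
#'
#' Replicate \code{i} uses the seed \code{deriveSeed(masterSeed, i)}, so
#' each replicate is individually reproducible and replicates can be
#' generated in any order with identical results.
#'
#' @inheritParams drawSubsample
#' @param nReplicates number of replicates (>= 1). The original analysis
#'   scale is 100,000; desk-scale runs use far fewer.
#' @param masterSeed integer master seed.
#' @return list of \code{"SubsampleReplicate"} objects.
#' @export
replicateSubsamples <- function(plots, minSeparationKm, nReplicates,
                                masterSeed) {
  nReplicates <- as.integer(nReplicates)
  if (is.na(nReplicates) || nReplicates < 1L)
    stop("nReplicates must be >= 1")
  lapply(seq_len(nReplicates), function(i) {
    r <- drawSubsample(plots, minSeparationKm, deriveSeed(masterSeed, i))
    r$replicateIndex <- i
    r
  })
}
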