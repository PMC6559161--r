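#' @include elevation-raster.R plot-communities.R seeds.R
NULL

#' Generate a fractal elevation surface
#'
#' Synthesizes a random elevation grid by Fourier spectral synthesis:
#' independent Gaussian coefficients are scaled by
#' \code{frequency^(-spectralExponent/2)}, inverse-transformed, and the
#' result is affinely rescaled to the requested mean and marginal
#' standard deviation. Larger \code{spectralExponent} concentrates power
#' at low frequencies and so increases spatial autocorrelation;
#' \code{spectralExponent = 3} gives terrain-like (fBm, H = 0.5) surfaces.
#' The rescaling is exact, so the sample SD of the cells equals
#' \code{sdTarget} up to floating point.
#'
#' @param nx,ny cell counts (>= 2).
#' @param cellSize cell edge length in metres.
#' @param spectralExponent power-spectrum slope (unitless, >= 0).
#' @param sdTarget marginal SD of elevation in metres (>= 0); 0 yields a
#'   constant surface at \code{meanElev}.
#' @param meanElev mean elevation in metres.
#' @param origin x, y of the upper-left grid corner (default places the
#'   lower-left corner at (0, 0)).
#' @param seed integer seed; identical specs give bit-identical rasters.
#' @return An [ElevationRaster-class] (projected mode).
#' @examples
#' r <- generateElevationSurface(64, 64, cellSize = 100,
#'                               spectralExponent = 3, sdTarget = 150,
#'                               meanElev = 1000, seed = 1)
#' sd(rasterValues(r))
#' @export
generateElevationSurface <- function(nx, ny, cellSize = 30,
                                     spectralExponent = 3, sdTarget = 150,
                                     meanElev = 1000,
                                     origin = c(0, ny * cellSize),
                                     seed = 1) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.na(nx) || is.na(ny) || nx < 2L || ny < 2L)
    stop("nx and ny must be integers >= 2")
  if (!is.finite(cellSize) || cellSize <= 0) stop("cellSize must be > 0")
  if (!is.finite(sdTarget) || sdTarget < 0) stop("sdTarget must be >= 0")

  if (sdTarget == 0) {
    z <- matrix(meanElev, ny, nx)
    return(ElevationRaster(z, origin = origin, cellSize = cellSize))
  }

  z <- withSeed(seed, {
    kx <- seq_len(nx) - 1L; kx <- ifelse(kx > nx / 2, kx - nx, kx)
    ky <- seq_len(ny) - 1L; ky <- ifelse(ky > ny / 2, ky - ny, ky)
    f <- sqrt(outer((ky / ny)^2, (kx / nx)^2, "+"))
    amp <- f^(-spectralExponent / 2)
    amp[1, 1] <- 0  # zero the DC component; the mean is set afterwards
    coef <- matrix(stats::rnorm(ny * nx), ny, nx) * amp +
      1i * matrix(stats::rnorm(ny * nx), ny, nx) * amp
    Re(stats::fft(coef, inverse = TRUE))
  })
  z <- meanElev + (z - mean(z)) * (sdTarget / stats::sd(as.vector(z)))
  ElevationRaster(z, origin = origin, cellSize = cellSize)
}
#' Generate a niche-assembled plot network on an elevation surface
#'
#' Places \code{nPlots} plots uniformly at random in \code{region} and
#' assembles each plot's tree community from three ingredients:
#' \enumerate{
#'   \item elevation niches — each species in the pool receives an
#'     elevation optimum uniform over the raster's elevation range, and
#'     the suitability of species s at plot p is
#'     \code{exp(-(e - opt_s)^2 / (2 nicheBreadth^2))}, evaluated at the
#'     plot's microsite elevations and maximised over microsites;
#'   \item geographic ranges — each species also carries two smooth
#'     random fields over the region: an occupancy field, thresholded to
#'     decide presence (probability \code{occupancy * suitability}, but
#'     spatially correlated, so nearby plots agree on which species are
#'     present, as patchy real ranges do), and a dominance field giving
#'     the spatially coherent part of its log basal area
#'     (\code{rangeShare} of the log-scale variance);
#'   \item a dominance lottery — the remaining log-abundance variance is
#'     idiosyncratic per plot and species. Plot totals are normalized to
#'     a common stocking level (mean-one lognormal, log-SD 0.3), so
#'     dominance structure, not total basal area, differs among plots.
#' }
#'
#' Terrain heterogeneity enters through three channels, each scaled by
#' \code{heterogeneityEffect / 3} and by the plot's relative local
#' relief \code{rel_p} (SD of elevation within \code{localWindowKm},
#' divided by the network mean):
#' \itemize{
#'   \item occupancy rises with relief
#'     (\code{baseOccupancy * (1 + g (rel_p - 1))}, clipped to
#'     \code{[0.02, 0.95]}) — rugged plots host more of the pool, the
#'     local-richness link the knob is defined by;
#'   \item microsite elevations spread as \code{N(elev_p, g * 3 *
#'     sdLocal_p)} — rugged plots sample more of the elevation gradient
#'     (locally widened effective niche breadth) and neighbouring rugged
#'     plots sample it differently;
#'   \item the idiosyncratic log-abundance SD rises with relief
#'     (\code{abundanceLognormSigma * (1 + g (rel_p - 1))}, floored at
#'     0.1) — stand dominance in rugged terrain is more of a lottery, so
#'     abundance-weighted turnover rises.
#' }
#' With \code{heterogeneityEffect = 0} all three channels are flat and
#' the community carries no built-in diversity-relief link.
#'
#' Plots whose community comes out empty are dropped.
#'
#' @param raster an [ElevationRaster-class] covering \code{region}.
#' @param nPlots number of plots to place (>= 1).
#' @param region numeric(4) \code{c(xmin, xmax, ymin, ymax)} in metres;
#'   must lie inside the raster footprint. Default: the raster footprint.
#' @param poolSize species pool size (>= 1).
#' @param nicheBreadth Gaussian niche SD on the elevation axis, metres.
#' @param abundanceLognormSigma log-scale SD of the idiosyncratic
#'   basal-area noise.
#' @param heterogeneityEffect strength of the local-heterogeneity link
#'   (unitless, >= 0); 0 disables it, 3 gives unit channel gains.
#' @param baseOccupancy presence probability at perfect suitability.
#' @param nMicrosites microsite draws per plot.
#' @param localWindowKm radius of the local-relief window (km).
#' @param rangeShare share (0..1) of log-abundance SD carried by the
#'   spatially coherent dominance field.
#' @param seed integer seed; identical specs give identical networks.
#' @return A [PlotCommunitySet-class] (projected mode).
#' @export
generatePlotNetwork <- function(raster, nPlots, region = NULL,
                                poolSize = 60, nicheBreadth = 300,
                                abundanceLognormSigma = 1,
                                heterogeneityEffect = 0,
                                baseOccupancy = 0.35, nMicrosites = 4,
                                localWindowKm = 10, rangeShare = 0.7,
                                seed = 1) {
  stopifnot(methods::is(raster, "ElevationRaster"))
  nPlots <- as.integer(nPlots)
  if (is.na(nPlots) || nPlots < 1L) stop("nPlots must be >= 1")
  if (poolSize < 1L) stop("poolSize must be >= 1")
  if (!is.finite(nicheBreadth) || nicheBreadth <= 0)
    stop("nicheBreadth must be > 0")
  if (rangeShare < 0 || rangeShare >= 1) stop("rangeShare must be in [0, 1)")
  fp <- rasterFootprint(raster)
  if (is.null(region)) region <- c(fp["xmin"], fp["xmax"], fp["ymin"], fp["ymax"])
  region <- as.numeric(region)
  if (region[1] < fp["xmin"] - 1e-9 || region[2] > fp["xmax"] + 1e-9 ||
      region[3] < fp["ymin"] - 1e-9 || region[4] > fp["ymax"] + 1e-9)
    stop("region must lie inside the raster footprint")

  ev <- rasterValues(raster)
  erange <- range(ev, na.rm = TRUE)
  g <- heterogeneityEffect / 3   # unit channel gain at effect = 3

  withSeed(seed, {
    px <- stats::runif(nPlots, region[1], region[2])
    py <- stats::runif(nPlots, region[3], region[4])
    elev <- elevationAt(raster, px, py)
    micro <- matrix(stats::rnorm(nPlots * nMicrosites), nPlots, nMicrosites)
    opt <- stats::runif(poolSize, erange[1], erange[2])
    # per-species smooth fields: occupancy threshold noise and dominance
    occField <- vapply(seq_len(poolSize), function(s)
      sampleSmoothField(px, py, region), numeric(nPlots))
    domField <- vapply(seq_len(poolSize), function(s)
      sampleSmoothField(px, py, region), numeric(nPlots))
    occField <- matrix(occField, nPlots, poolSize)
    domField <- matrix(domField, nPlots, poolSize)
    idio <- matrix(stats::rnorm(nPlots * poolSize), nPlots, poolSize)
    totDraw <- stats::rnorm(nPlots)

    sdLoc <- vapply(seq_len(nPlots), function(i) {
      w <- windowValues(raster, c(px[i], py[i]), radiusKm = localWindowKm)
      if (length(w$values) >= 2L) stats::sd(w$values) else 0
    }, numeric(1))
    relRelief <- if (mean(sdLoc) > 0) sdLoc / mean(sdLoc) else rep(1, nPlots)

    micro <- elev + g * 3 * sdLoc * micro  # recycled by row

    suit <- matrix(0, nPlots, poolSize)
    for (k in seq_len(nMicrosites)) {
      sk <- exp(-(outer(micro[, k], opt, "-"))^2 / (2 * nicheBreadth^2))
      suit <- pmax(suit, sk)
    }
    suit[is.na(suit)] <- 0  # plots landing on nodata cells stay empty

    occ <- pmin(0.95, pmax(0.02,
      baseOccupancy * (1 + g * (relRelief - 1))))
    present <- stats::pnorm(occField) < occ * suit
    idioSD <- pmax(0.1,
      abundanceLognormSigma * (1 + g * (relRelief - 1)))
    lnA <- rangeShare * abundanceLognormSigma * domField +
      sqrt(1 - rangeShare^2) * idioSD * idio  # idioSD recycled by row
    ba <- suit * exp(lnA)
    ba[!present] <- 0

    tot <- rowSums(ba)
    keep <- tot > 0
    # normalize plot totals to a mean-one lognormal stocking level
    ba <- ba / ifelse(tot > 0, tot, 1) * exp(0.3 * totDraw - 0.045)
    abund <- t(ba[keep, , drop = FALSE])
    rownames(abund) <- sprintf("SP%03d", seq_len(poolSize))
    colnames(abund) <- sprintf("P%04d", which(keep))
    coords <- cbind(x = px[keep], y = py[keep])
    out <- PlotCommunitySet(abund, coords)
    attr(out@coords, "droppedEmpty") <- sum(!keep)
    out
  })
}

# standard-normal smooth random field over the region rectangle, sampled
# at the given points; 64x64 spectral grid with power-spectrum slope 3
# (range patches with correlation length a modest fraction of the extent)
sampleSmoothField <- function(px, py, region, m = 64L, expo = 3) {
  kx <- seq_len(m) - 1L
  kx <- ifelse(kx > m / 2, kx - m, kx)
  f <- sqrt(outer((kx / m)^2, (kx / m)^2, "+"))
  amp <- f^(-expo / 2)
  amp[1, 1] <- 0
  coefr <- matrix(stats::rnorm(m * m), m, m)
  coefi <- matrix(stats::rnorm(m * m), m, m)
  z <- Re(stats::fft((coefr + 1i * coefi) * amp, inverse = TRUE))
  z <- (z - mean(z)) / stats::sd(as.vector(z))
  i <- pmin(m, pmax(1L, ceiling((py - region[3]) /
                                  (region[4] - region[3]) * m)))
  j <- pmin(m, pmax(1L, ceiling((px - region[1]) /
                                  (region[2] - region[1]) * m)))
  z[cbind(i, j)]
}

#' Simulate directly from the fitted-model families
#'
#' Draws (x, y) pairs from exactly the regression families the pipeline
#' fits, so model-recovery tests do not depend on the community
#' generator: \code{"gamma-log"} gives y ~ Gamma(mean = exp(beta0 +
#' beta1 x), shape = shapeOrPrecision); \code{"beta-logit"} gives y ~
#' Beta(mu phi, (1 - mu) phi) with mu = plogis(beta0 + beta1 x) and phi =
#' shapeOrPrecision. x is uniform on \code{xRange}.
#'
#' @param family \code{"gamma-log"} or \code{"beta-logit"}.
#' @param beta0,beta1 link-scale intercept and slope.
#' @param shapeOrPrecision gamma shape nu or beta precision phi (> 0).
#' @param n sample count (>= 2).
#' @param xRange numeric(2), range of the predictor (metres of
#'   elevation SD).
#' @param seed integer seed.
#' @return data.frame with columns \code{x}, \code{y}.
#' @examples
#' head(generateResponseTable("gamma-log", 0.5, 0.005, 10, n = 5, seed = 1))
#' @export
generateResponseTable <- function(family = c("gamma-log", "beta-logit"),
                                  beta0, beta1, shapeOrPrecision, n,
                                  xRange = c(0, 200), seed = 1) {
  family <- match.arg(family)
  if (!is.finite(shapeOrPrecision) || shapeOrPrecision <= 0)
    stop("shapeOrPrecision must be > 0")
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be >= 2")
  withSeed(seed, {
    x <- stats::runif(n, xRange[1], xRange[2])
    eta <- beta0 + beta1 * x
    y <- if (family == "gamma-log") {
      mu <- exp(eta)
      stats::rgamma(n, shape = shapeOrPrecision, rate = shapeOrPrecision / mu)
    } else {
      mu <- stats::plogis(eta)
      stats::rbeta(n, mu * shapeOrPrecision, (1 - mu) * shapeOrPrecision)
    }
    data.frame(x = x, y = y)
  })
}
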