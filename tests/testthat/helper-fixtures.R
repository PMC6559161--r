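# shared in-code fixtures

# PlotCommunitySet from a named list of abundance vectors + coordinates
makePCS <- function(comms, coords = NULL, crsMode = "projected") {
  sp <- sort(unique(unlist(lapply(comms, names))))
  a <- sapply(comms, function(v) {
    out <- stats::setNames(numeric(length(sp)), sp)
    out[names(v)] <- v
    out
  })
  a <- matrix(a, nrow = length(sp),
              dimnames = list(sp, names(comms)))
  if (is.null(coords))
    coords <- cbind(x = seq_along(comms) * 1000, y = rep(0, length(comms)))
  PlotCommunitySet(a, coords, crsMode = crsMode)
}

# small flat-ish raster with known values
makeRaster <- function(values, cellSize = 1, origin = NULL, ...) {
  m <- as.matrix(values)
  if (is.null(origin)) origin <- c(0, nrow(m) * cellSize)
  ElevationRaster(m, origin = origin, cellSize = cellSize, ...)
}

# random neighbourhood for property tests: n plots, pool of s species
randomNeighborhood <- function(n, s, seed) {
  set.seed(seed)
  comms <- lapply(seq_len(n), function(i) {
    k <- sample(s, sample(1:s, 1))
    stats::setNames(stats::rexp(length(k)), paste0("S", k))
  })
  names(comms) <- paste0("p", seq_len(n))
  makePCS(comms)
}

# independent Nelder-Mead maximization of the gamma-GLM likelihood
# (oracle; deliberately separate from the package's IRLS path)
oracleGammaFit <- function(x, y) {
  nll <- function(th) {
    mu <- exp(th[1] + th[2] * x)
    nu <- exp(th[3])
    -sum(stats::dgamma(y, shape = nu, rate = nu / mu, log = TRUE))
  }
  start <- c(log(mean(y)), 0, 0)
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  opt <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  list(beta = opt$par[1:2], shape = exp(opt$par[3]), loglik = -opt$value)
}

# independent Nelder-Mead maximization of the beta-regression likelihood
oracleBetaFit <- function(x, y) {
  nll <- function(th) {
    mu <- stats::plogis(th[1] + th[2] * x)
    phi <- exp(th[3])
    -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  start <- c(0, 0, log(5))
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 10000, reltol = 1e-14))
  opt <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                      control = list(maxit = 10000, reltol = 1e-14))
  list(beta = opt$par[1:2], phi = exp(opt$par[3]), loglik = -opt$value)
}
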