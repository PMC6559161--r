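test_that("elevation surface hits its target moments exactly", {
  r <- generateElevationSurface(64, 48, cellSize = 100,
                                spectralExponent = 3, sdTarget = 120,
                                meanElev = 900, seed = 3)
  v <- rasterValues(r)
  expect_equal(dim(v), c(48, 64))
  expect_equal(sd(as.vector(v)), 120, tolerance = 1e-10)
  expect_equal(mean(v), 900, tolerance = 1e-9)
})

test_that("zero-variance surface is constant at the mean elevation", {
  r <- generateElevationSurface(8, 8, sdTarget = 0, meanElev = 1234, seed = 1)
  expect_true(all(rasterValues(r) == 1234))
})

test_that("surfaces are bit-identical under the same seed", {
  a <- generateElevationSurface(32, 32, sdTarget = 100, seed = 17)
  b <- generateElevationSurface(32, 32, sdTarget = 100, seed = 17)
  expect_identical(rasterValues(a), rasterValues(b))
  c <- generateElevationSurface(32, 32, sdTarget = 100, seed = 18)
  expect_false(identical(rasterValues(a), rasterValues(c)))
})

test_that("spectral exponent controls spatial autocorrelation", {
  lag1 <- function(expo, seed) {
    v <- rasterValues(generateElevationSurface(
      128, 128, spectralExponent = expo, sdTarget = 100, seed = seed))
    cor(as.vector(v[, -1]), as.vector(v[, -ncol(v)]))
  }
  diffs <- vapply(1:20, function(s) lag1(3, s) - lag1(0, s), numeric(1))
  expect_true(all(diffs > 0))
})

test_that("surface generator rejects invalid specs", {
  expect_error(generateElevationSurface(1, 8), ">= 2")
  expect_error(generateElevationSurface(8, 8, cellSize = 0), "cellSize")
  expect_error(generateElevationSurface(8, 8, sdTarget = -1), "sdTarget")
})

test_that("plot networks are deterministic and respect the region", {
  r <- generateElevationSurface(80, 80, cellSize = 250, sdTarget = 200,
                                seed = 5)
  p1 <- generatePlotNetwork(r, 60, poolSize = 20, seed = 9)
  p2 <- generatePlotNetwork(r, 60, poolSize = 20, seed = 9)
  expect_identical(as.matrix(abundanceMatrix(p1)),
                   as.matrix(abundanceMatrix(p2)))
  expect_identical(plotCoords(p1), plotCoords(p2))
  xy <- plotCoords(p1)
  expect_true(all(xy[, 1] >= 0 & xy[, 1] <= 20000 &
                    xy[, 2] >= 0 & xy[, 2] <= 20000))
  expect_error(
    generatePlotNetwork(r, 10, region = c(-1e5, 1e5, 0, 1e4), seed = 1),
    "inside the raster")
})

test_that("a single-species pool gives monocultures everywhere", {
  r <- generateElevationSurface(40, 40, cellSize = 250, sdTarget = 150,
                                seed = 2)
  p <- generatePlotNetwork(r, 50, poolSize = 1, baseOccupancy = 0.9,
                           nicheBreadth = 5000, seed = 3)
  rich <- Matrix::colSums(abundanceMatrix(p) > 0)
  expect_true(all(rich == 1))
  expect_true(all(vapply(seq_len(nPlots(p)), function(i)
    alphaDiversity(p[i]), numeric(1)) == 1))
})

test_that("the heterogeneity effect links richness to local relief", {
  # effect 5 vs 0: mean richness in top-quartile local-relief terrain
  # exceeds the bottom quartile only when the effect is on
  contrast <- function(effect, s) {
    r <- generateElevationSurface(400, 400, cellSize = 250,
                                  spectralExponent = 3.5, sdTarget = 300,
                                  meanElev = 1200, seed = 500 + s)
    p <- generatePlotNetwork(r, 120, heterogeneityEffect = effect, seed = s)
    xy <- plotCoords(p)
    sdl <- vapply(seq_len(nrow(xy)), function(i)
      sdElevation(windowValues(r, xy[i, ], 10)$values), numeric(1))
    rich <- Matrix::colSums(abundanceMatrix(p) > 0)
    q <- quantile(sdl, c(0.25, 0.75))
    mean(rich[sdl >= q[2]]) - mean(rich[sdl <= q[1]])
  }
  withQ <- vapply(1:12, function(s) contrast(5, s), numeric(1))
  without <- vapply(1:12, function(s) contrast(0, s), numeric(1))
  expect_gt(mean(withQ), 1)                  # clear contrast with effect on
  expect_gt(mean(withQ), mean(without) + 1)  # and only with effect on
  expect_lt(abs(mean(without)), 1)
})

test_that("response tables follow their generating families", {
  d <- generateResponseTable("gamma-log", 0.5, 0, 10, n = 10000,
                             xRange = c(0, 100), seed = 12)
  expect_true(all(d$y > 0))
  # LLN: mean within 3 Monte-Carlo SEs of exp(beta0)
  se <- sd(d$y) / sqrt(nrow(d))
  expect_lt(abs(mean(d$y) - exp(0.5)), 3 * se)

  b <- generateResponseTable("beta-logit", 0, 0, 8, n = 10000, seed = 13)
  expect_true(all(b$y > 0 & b$y < 1))
  expect_lt(abs(mean(b$y) - 0.5), 3 * sd(b$y) / sqrt(nrow(b)))

  expect_identical(generateResponseTable("gamma-log", 1, 0.01, 5, 50, seed = 3),
                   generateResponseTable("gamma-log", 1, 0.01, 5, 50, seed = 3))
  expect_error(generateResponseTable("poisson", 1, 0, 1, 10), "arg")
  expect_error(generateResponseTable("gamma-log", 1, 0, -1, 10),
               "shapeOrPrecision")
})
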