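test_that("edge filter keeps interior plots and drops border plots", {
  # 400 x 400 km square; one central plot, one 50 km from an edge
  pcs <- makePCS(list(center = c(A = 1), nearEdge = c(A = 1)),
                 coords = cbind(x = c(200e3, 50e3), y = c(200e3, 200e3)))
  box <- c(0, 400e3, 0, 400e3)
  kept <- suppressMessages(filterEdgePlots(pcs, box, 100))
  expect_equal(plotIds(kept), "center")
  # buffer 0 retains everything inside
  expect_equal(nPlots(suppressMessages(filterEdgePlots(pcs, box, 0))), 2L)
  # plots outside the boundary polygon are dropped regardless
  pcs2 <- makePCS(list(out = c(A = 1)),
                  coords = cbind(x = 900e3, y = 900e3))
  expect_error(suppressMessages(filterEdgePlots(pcs2, box, 0)), "no plots")
  # polygon ring input behaves like the bounding box
  ring <- cbind(x = c(0, 400e3, 400e3, 0), y = c(0, 0, 400e3, 400e3))
  expect_equal(plotIds(suppressMessages(filterEdgePlots(pcs, ring, 100))),
               "center")
})

test_that("neighbourhoods use an inclusive radius and always hold the focal plot", {
  pcs <- makePCS(list(f = c(A = 1), near = c(B = 1), far = c(C = 1)),
                 coords = cbind(x = c(0, 4900, 5100), y = c(0, 0, 0)))
  n0 <- neighborhoodMembers(pcs, "f", 0)
  expect_equal(plotIds(n0), "f")
  n5 <- neighborhoodMembers(pcs, "f", 5)
  expect_setequal(plotIds(n5), c("f", "near"))
  # exact boundary is inclusive
  nEdge <- neighborhoodMembers(pcs, "f", 4.9)
  expect_setequal(plotIds(nEdge), c("f", "near"))
  expect_error(neighborhoodMembers(pcs, "nope", 5), "not found")
})

test_that("lattice neighbourhood at one grid spacing is focal + rook neighbours", {
  xy <- expand.grid(x = seq(0, 40e3, 10e3), y = seq(0, 40e3, 10e3))
  comms <- setNames(lapply(seq_len(nrow(xy)), function(i) c(A = 1)),
                    paste0("g", seq_len(nrow(xy))))
  pcs <- makePCS(comms, coords = as.matrix(xy))
  center <- which(xy$x == 20e3 & xy$y == 20e3)
  nb <- neighborhoodMembers(pcs, paste0("g", center), 10)
  expect_equal(nPlots(nb), 5L)
})

test_that("scale table covers every plot x radius with hand-checked values", {
  # three plots within 5 km; compositions {A:1}, {B:1}, {A:1}
  pcs <- makePCS(list(p1 = c(A = 1), p2 = c(B = 1), p3 = c(A = 1)),
                 coords = cbind(x = c(0, 1000, 2000), y = c(0, 0, 0)))
  r <- makeRaster(matrix(rep(c(100, 200), 8), 4, 4), cellSize = 1000,
                  origin = c(-1000, 2000))
  st <- buildScaleTable(pcs, r, c(5, 10))
  expect_equal(nrow(st), 6L)
  expect_equal(st$n_plots_in_radius[st$radius_km == 5], c(3L, 3L, 3L))
  row1 <- st[st$plot_id == "p1" & st$radius_km == 5, ]
  # pooled {A:2, B:1}: gamma = exp(-(2/3)ln(2/3) - (1/3)ln(1/3))
  expect_equal(row1$gamma, 1.88988157, tolerance = 1e-7)
  expect_equal(row1$beta, 2 / 3, tolerance = 1e-12)
  expect_equal(row1$alpha, 1)
  # n_plots_in_radius is non-decreasing in radius per focal plot
  for (id in plotIds(pcs)) {
    ni <- st$n_plots_in_radius[st$plot_id == id]
    expect_true(all(diff(ni) >= 0))
  }
})

test_that("single and duplicated plots give the degenerate table rows", {
  lone <- makePCS(list(solo = c(A = 2, B = 1)),
                  coords = cbind(x = 5000, y = 5000))
  r <- makeRaster(matrix(100, 12, 12), cellSize = 1000)
  st <- buildScaleTable(lone, r, c(2))
  expect_equal(st$alpha, st$gamma)
  expect_true(is.na(st$beta))
  expect_equal(st$sd_elev, 0)
  # two co-located identical plots: beta 0, gamma = alpha
  twin <- makePCS(list(t1 = c(A = 2, B = 1), t2 = c(A = 2, B = 1)),
                  coords = cbind(x = c(5000, 5000), y = c(5000, 5000)))
  st2 <- buildScaleTable(twin, r, c(2))
  expect_equal(st2$beta, c(0, 0))
  expect_equal(st2$gamma, st2$alpha)
})

test_that("gamma stays within its algebraic bounds on random tables", {
  pcs <- randomNeighborhood(12, 6, seed = 77)
  # spread plots so neighbourhood composition varies with radius
  pcs@coords[, 1] <- seq(0, 22e3, length.out = 12)
  r <- makeRaster(matrix(rnorm(900, 500, 50), 30, 30), cellSize = 1000,
                  origin = c(-2000, 14000))
  st <- buildScaleTable(pcs, r, c(2, 6, 12))
  expect_true(all(st$gamma >= 1))
  a <- as.matrix(abundanceMatrix(pcs))
  for (k in seq_len(nrow(st))) {
    nb <- neighborhoodMembers(pcs, st$plot_id[k], st$radius_km[k])
    richness <- sum(Matrix::rowSums(abundanceMatrix(nb)) > 0)
    expect_lte(st$gamma[k], richness + 1e-9)
  }
  expect_equal(nrow(st), 12 * 3)
})

test_that("CRS mismatches are refused", {
  pcs <- makePCS(list(p = c(A = 1)), coords = cbind(x = 1, y = 1),
                 crsMode = "geographic")
  r <- makeRaster(matrix(1, 4, 4), cellSize = 1000)
  expect_error(buildScaleTable(pcs, r, 5), "CRS")
})
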