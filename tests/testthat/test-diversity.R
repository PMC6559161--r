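test_that("effective species number matches Hill-number identities", {
  expect_equal(effectiveSpeciesNumber(c(1, 1, 1, 1)), 4)
  expect_equal(effectiveSpeciesNumber(5), 1)
  # exp(-(0.7 ln 0.7 + 0.3 ln 0.3)), hand-evaluated
  expect_equal(effectiveSpeciesNumber(c(0.7, 0.3)), 1.84202279,
               tolerance = 1e-7)
  # zero abundances contribute nothing
  expect_equal(effectiveSpeciesNumber(c(0.7, 0.3, 0, 0)),
               effectiveSpeciesNumber(c(0.7, 0.3)))
  expect_error(effectiveSpeciesNumber(c(0, 0)), "positive")
  expect_error(effectiveSpeciesNumber(c(-1, 2)), "non-negative")
})

test_that("alpha diversity is the median per-plot effective species number", {
  # per-plot D = 1, 2, 4 -> median 2
  pcs <- makePCS(list(p1 = c(A = 1),
                      p2 = c(A = 1, B = 1),
                      p3 = c(A = 1, B = 1, C = 1, D = 1)))
  expect_equal(alphaDiversity(pcs), 2)
  expect_equal(alphaDiversity(pcs[1]), 1)
  # even count: mean of the two central values
  pcs2 <- makePCS(list(p1 = c(A = 1), p2 = c(A = 1, B = 1, C = 1)))
  expect_equal(alphaDiversity(pcs2), 2)
})

test_that("Bray-Curtis endpoints and hand example", {
  expect_equal(pairwiseDissimilarity(c(A = 1, B = 2), c(A = 1, B = 2)), 0)
  expect_equal(pairwiseDissimilarity(c(A = 1), c(B = 3)), 1)
  expect_equal(pairwiseDissimilarity(c(A = 2, B = 1), c(A = 1, B = 2)),
               1 / 3, tolerance = 1e-12)
  # symmetric
  expect_equal(pairwiseDissimilarity(c(A = 2, B = 1), c(A = 1, B = 2)),
               pairwiseDissimilarity(c(A = 1, B = 2), c(A = 2, B = 1)))
  expect_error(pairwiseDissimilarity(c(A = 0), c(A = 1)), "positive total")
  # proportion variant removes between-plot weighting
  expect_equal(pairwiseDissimilarity(c(A = 10), c(A = 1), proportions = TRUE), 0)
})

test_that("beta diversity averages all pairs and is NA for single plots", {
  two <- makePCS(list(p1 = c(A = 1), p2 = c(A = 1)))
  expect_equal(betaDiversity(two), 0)
  expect_true(is.na(betaDiversity(two[1])))
  three <- makePCS(list(p1 = c(A = 1), p2 = c(B = 1), p3 = c(A = 1)))
  expect_equal(betaDiversity(three), 2 / 3, tolerance = 1e-12)
})

test_that("gamma diversity pools basal areas species-wise", {
  expect_equal(gammaDiversity(makePCS(list(p1 = c(A = 1), p2 = c(B = 1)))), 2)
  # pooled {A:2,B:2,C:2} -> 3 equally abundant species
  expect_equal(gammaDiversity(makePCS(list(p1 = c(A = 2, B = 1),
                                           p2 = c(B = 1, C = 2)))), 3)
  # pooling identical plots leaves D unchanged
  same <- makePCS(list(p1 = c(A = 2, B = 1), p2 = c(A = 2, B = 1),
                       p3 = c(A = 2, B = 1)))
  expect_equal(gammaDiversity(same), effectiveSpeciesNumber(c(2, 1)))
})

test_that("order-1 partitioning: pooled gamma bounds the weighted geometric mean of alphas", {
  for (i in 1:250) {
    pcs <- randomNeighborhood(n = sample(2:6, 1), s = sample(2:8, 1),
                              seed = 1000 + i)
    a <- as.matrix(abundanceMatrix(pcs))
    d <- apply(a, 2, effectiveSpeciesNumber)
    w <- colSums(a) / sum(a)
    gm <- exp(sum(w * log(d)))
    expect_gte(gammaDiversity(pcs), gm - 1e-10)
  }
})

test_that("metrics are invariant to species/plot order and common rescaling", {
  pcs <- randomNeighborhood(5, 6, seed = 7)
  a <- as.matrix(abundanceMatrix(pcs))
  perm <- makePCS(setNames(
    lapply(sample(ncol(a)), function(j) {
      v <- a[sample(nrow(a)), j]
      v[v > 0]
    }), paste0("q", seq_len(ncol(a)))))
  expect_equal(alphaDiversity(perm), alphaDiversity(pcs))
  expect_equal(betaDiversity(perm), betaDiversity(pcs), tolerance = 1e-12)
  expect_equal(gammaDiversity(perm), gammaDiversity(pcs), tolerance = 1e-12)
  # common rescaling of ALL basal areas by c > 0
  scaled <- PlotCommunitySet(abundanceMatrix(pcs) * 3.7, plotCoords(pcs))
  expect_equal(alphaDiversity(scaled), alphaDiversity(pcs))
  expect_equal(betaDiversity(scaled), betaDiversity(pcs), tolerance = 1e-12)
  expect_equal(gammaDiversity(scaled), gammaDiversity(pcs), tolerance = 1e-12)
})

test_that("beta diversity stays in the unit interval", {
  for (i in 1:50) {
    pcs <- randomNeighborhood(sample(2:5, 1), sample(2:6, 1), seed = 300 + i)
    b <- betaDiversity(pcs)
    expect_true(b >= 0 && b <= 1)
  }
})
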