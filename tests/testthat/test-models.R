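test_that("gamma GLM reproduces a noiseless log-linear relationship", {
  x <- seq(0, 300, length.out = 40)
  y <- exp(1 + 0.01 * x)
  fit <- fitGammaGLM(x, y)
  expect_true(isConverged(fit))
  expect_equal(unname(coef(fit)), c(1, 0.01), tolerance = 1e-6)
  expect_equal(pseudoR2(fit, x, y), 1, tolerance = 1e-8)
})

test_that("gamma GLM agrees with stats::glm and recovers the truth", {
  d <- generateResponseTable("gamma-log", 0.5, 0.005, 10, n = 1000, seed = 21)
  fit <- fitGammaGLM(d$x, d$y)
  ref <- glm(y ~ x, data = d, family = Gamma(link = "log"))
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  # recovery within 3 asymptotic SEs of the generating values
  se <- sqrt(diag(vcov(ref)))
  expect_lt(abs(coef(fit)[1] - 0.5), 3 * se[1])
  expect_lt(abs(coef(fit)[2] - 0.005), 3 * se[2])
  expect_gt(modelAux(fit), 0)
})

test_that("gamma GLM matches brute-force likelihood maximization on n = 20", {
  d <- generateResponseTable("gamma-log", 0.8, 0.008, 6, n = 20, seed = 5)
  fit <- fitGammaGLM(d$x, d$y)
  oracle <- oracleGammaFit(d$x, d$y)
  expect_equal(unname(coef(fit)), oracle$beta, tolerance = 1e-4)
  expect_equal(modelAux(fit), oracle$shape, tolerance = 1e-3)
  expect_gte(logLikelihood(fit), oracle$loglik - 1e-6)
})

test_that("beta regression recovers simulated parameters", {
  d <- generateResponseTable("beta-logit", -1, 0.02, 50, n = 2000, seed = 31)
  fit <- fitBetaRegression(d$x, d$y)
  expect_true(isConverged(fit))
  # asymptotic SEs from the numeric Hessian of the log-likelihood
  nll <- function(th) -sum(dbeta(d$y, plogis(th[1] + th[2] * d$x) * th[3],
                                 (1 - plogis(th[1] + th[2] * d$x)) * th[3],
                                 log = TRUE))
  H <- optimHess(c(coef(fit), modelAux(fit)), nll)
  se <- sqrt(diag(solve(H)))
  expect_lt(abs(coef(fit)[1] - (-1)), 3 * se[1])
  expect_lt(abs(coef(fit)[2] - 0.02), 3 * se[2])
  expect_lt(abs(modelAux(fit) - 50), 3 * se[3])
  # MLE dominates the generating parameters on the sample
  expect_gte(logLikelihood(fit),
             -nll(c(-1, 0.02, 50)))
})

test_that("beta regression matches brute-force likelihood maximization on n = 20", {
  d <- generateResponseTable("beta-logit", -0.5, 0.015, 20, n = 20, seed = 8)
  fit <- fitBetaRegression(d$x, d$y)
  oracle <- oracleBetaFit(d$x, d$y)
  expect_equal(unname(coef(fit)), oracle$beta, tolerance = 1e-4)
  expect_equal(modelAux(fit), oracle$phi, tolerance = 1e-3)
  expect_gte(logLikelihood(fit), oracle$loglik - 1e-6)
})

test_that("both fitters ascend their likelihood at every iteration", {
  for (s in 1:5) {
    d <- generateResponseTable("gamma-log", 0.5, 0.005, 4, n = 50,
                               seed = 100 + s)
    expect_true(all(diff(fitGammaGLM(d$x, d$y)@trace) >= -1e-8))
    b <- generateResponseTable("beta-logit", -1, 0.02, 10, n = 50,
                               seed = 200 + s)
    expect_true(all(diff(fitBetaRegression(b$x, b$y)@trace) >= -1e-8))
  }
})

test_that("domain violations are rejected with directions", {
  expect_error(fitGammaGLM(1:10, c(-1, 2:10)), "positive")
  expect_error(fitBetaRegression(1:10, c(0, runif(9))),
               "squeezeUnitInterval")
  expect_error(fitGammaGLM(1:2, c(1, 2)), "3 observations")
  # constant predictor: flagged, not an error
  expect_false(isConverged(fitGammaGLM(rep(1, 10), rexp(10) + 0.1)))
})

test_that("unit-interval squeeze matches the Smithson-Verkuilen formula", {
  expect_equal(squeezeUnitInterval(0.5, 100), 0.5)
  expect_equal(squeezeUnitInterval(0, 20), 0.025)
  expect_equal(squeezeUnitInterval(1, 20), 0.975)
  y <- c(0, 0.2, 0.9, 1)
  ys <- squeezeUnitInterval(y, 10)
  expect_true(all(ys > 0 & ys < 1))
  expect_true(all(diff(ys[order(y)]) > 0))  # order preserving
  expect_error(squeezeUnitInterval(1.2, 10), "0, 1")
})

test_that("standardized slopes follow the marginal-effect construction", {
  gfit <- new("ModelFit", family = "gamma-log",
              coefficients = c(`(Intercept)` = log(10), x = 0.01),
              aux = 5, loglik = 0, converged = TRUE, n = 10L,
              trace = numeric(0))
  # beta1 * mu(x_ref) / sd_y with mu(0) = 10
  expect_equal(standardizedSlope(gfit, xRef = 0, sdY = 5), 0.02)
  bfit <- new("ModelFit", family = "beta-logit",
              coefficients = c(`(Intercept)` = 0, x = 0.02),
              aux = 50, loglik = 0, converged = TRUE, n = 10L,
              trace = numeric(0))
  # beta1 * mu (1 - mu) / sd_y at mu = 0.5
  expect_equal(standardizedSlope(bfit, xRef = 0, sdY = 0.1), 0.05)
  gfit0 <- gfit; gfit0@coefficients[2] <- 0
  expect_equal(standardizedSlope(gfit0, 10, 5), 0)
  expect_true(is.na(standardizedSlope(gfit, 0, 0)))
})

test_that("gamma-family standardized slope is invariant to rescaling y", {
  d <- generateResponseTable("gamma-log", 0.5, 0.004, 8, n = 300, seed = 77)
  f1 <- fitGammaGLM(d$x, d$y)
  f2 <- fitGammaGLM(d$x, d$y * 12)
  s1 <- standardizedSlope(f1, mean(d$x), sd(d$y))
  s2 <- standardizedSlope(f2, mean(d$x), sd(d$y * 12))
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("pseudo-R2 equals an independently computed deviance ratio", {
  d <- generateResponseTable("gamma-log", 0.5, 0.006, 5, n = 20, seed = 13)
  fit <- fitGammaGLM(d$x, d$y)
  mu <- predictMean(fit, d$x)
  devRes <- 2 * sum(-log(d$y / mu) + (d$y - mu) / mu)
  devNull <- 2 * sum(-log(d$y / mean(d$y)) + (d$y - mean(d$y)) / mean(d$y))
  expect_equal(pseudoR2(fit, d$x, d$y), 1 - devRes / devNull,
               tolerance = 1e-10)
  # beta family: squared link-scale correlation
  b <- generateResponseTable("beta-logit", -1, 0.02, 30, n = 50, seed = 14)
  bf <- fitBetaRegression(b$x, b$y)
  eta <- coef(bf)[1] + coef(bf)[2] * b$x
  expect_equal(pseudoR2(bf, b$x, b$y), cor(eta, qlogis(b$y))^2,
               tolerance = 1e-12)
})

test_that("replicate summaries use the linear-interpolation percentile convention", {
  mkRep <- function(slope) {
    fit <- new("ModelFit", family = "gamma-log",
               coefficients = c(`(Intercept)` = 1, x = slope / 10),
               aux = 5, loglik = 0, converged = TRUE, n = 10L,
               trace = numeric(0))
    list(fit = fit, slope = slope, pseudoR2 = 0.5, xRef = 0, sdY = 1,
         squeezed = FALSE)
  }
  reps <- lapply(1:100, mkRep)
  sm <- summarizeReplicates(reps, xGrid = c(0, 1), radiusKm = 5,
                            form = "gamma")
  expect_equal(unname(sm$slopePercentiles[["50%"]]), 50.5)
  expect_equal(unname(sm$slopePercentiles[["2.5%"]]),
               unname(quantile(1:100, 0.025)))
  expect_true(all(diff(sm$slopePercentiles) >= 0))
  expect_true(all(sm$band$lower <= sm$band$median + 1e-12) &&
                all(sm$band$median <= sm$band$upper + 1e-12))
  # permutation invariance in replicate order
  sm2 <- summarizeReplicates(reps[sample(100)], xGrid = c(0, 1), 5, "gamma")
  expect_equal(sm2$slopePercentiles, sm$slopePercentiles)
  # degenerate: identical replicates give zero-width percentiles
  smd <- summarizeReplicates(lapply(rep(2, 10), mkRep), xGrid = c(0, 1),
                             5, "gamma")
  expect_true(all(smd$slopePercentiles == 2))
  expect_equal(smd$band$lower, smd$band$upper)
})

test_that("fitScalingReplicate squeezes boundary beta values and reports flags", {
  set.seed(3)
  x <- runif(20, 0, 200)
  y <- c(0, runif(18, 0.2, 0.8), 1)
  rep <- fitScalingReplicate(x, y, "beta")
  expect_true(rep$squeezed)
  expect_true(isConverged(rep$fit))
  expect_equal(rep$sdY, sd(y))  # SD of the unsqueezed response
  expect_equal(rep$xRef, mean(x))
})
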