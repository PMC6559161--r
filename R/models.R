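#' @include AllClasses.R
NULL

# gamma log-likelihood at mean mu, shape nu
gammaLoglik <- function(y, mu, nu) {
  sum(stats::dgamma(y, shape = nu, rate = nu / mu, log = TRUE))
}

# gamma deviance, D = 2 sum(-log(y/mu) + (y - mu)/mu)
gammaDeviance <- function(y, mu) {
  2 * sum(-log(y / mu) + (y - mu) / mu)
}

#' Fit a gamma GLM with log link
#'
#' Maximum likelihood for \eqn{y \sim Gamma(mean = \exp(\beta_0 +
#' \beta_1 x), shape = \nu)}. The mean coefficients are estimated by
#' iteratively reweighted least squares (for the log link the IRLS
#' weights are constant, so each step is ordinary least squares on the
#' working response); under a gamma likelihood the mean estimate does not
#' depend on \eqn{\nu}, which is then profiled out by one-dimensional
#' maximum likelihood given the fitted means. Convergence: relative
#' deviance change < 1e-8 or 100 iterations. The deviance decreases at
#' every IRLS step, which is equivalent to ascent of the profile
#' log-likelihood; \code{trace} stores -deviance/2 per iteration.
#'
#' @param x predictor (metres of elevation SD); must not be constant.
#' @param y strictly positive response (effective species numbers).
#' @return A [ModelFit-class] with \code{family = "gamma-log"}. A fit
#'   that fails to converge is returned flagged (\code{isConverged}
#'   FALSE) so callers can exclude it from summaries.
#' @examples
#' d <- generateResponseTable("gamma-log", 0.5, 0.005, 10, n = 200, seed = 1)
#' fitGammaGLM(d$x, d$y)
#' @export
fitGammaGLM <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(y)
  if (n < 3L) stop("at least 3 observations are required")
  if (any(y <= 0)) stop("gamma GLM requires strictly positive y")
  if (stats::sd(x) == 0) {
    return(methods::new("ModelFit", family = "gamma-log",
                        coefficients = c(`(Intercept)` = NA_real_, x = NA_real_),
                        aux = NA_real_, loglik = NA_real_, converged = FALSE,
                        n = n, trace = numeric(0)))
  }
  X <- cbind(1, x)
  eta <- log(y)
  beta <- stats::lm.fit(X, eta)$coefficients
  eta <- drop(X %*% beta)
  dev <- gammaDeviance(y, exp(eta))
  trace <- -dev / 2
  converged <- FALSE
  for (it in seq_len(100L)) {
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    beta <- stats::lm.fit(X, z)$coefficients
    etaNew <- drop(X %*% beta)
    devNew <- gammaDeviance(y, exp(etaNew))
    # step-halve if a step overshoots, keeping the deviance monotone
    step <- 1
    while (devNew > dev && step > 1e-8) {
      step <- step / 2
      etaNew <- eta + step * (drop(X %*% beta) - eta)
      devNew <- gammaDeviance(y, exp(etaNew))
    }
    eta <- etaNew
    trace <- c(trace, -devNew / 2)
    if (abs(dev - devNew) / (abs(dev) + 0.1) < 1e-8) {
      dev <- devNew
      converged <- TRUE
      break
    }
    dev <- devNew
  }
  beta <- stats::lm.fit(X, eta)$coefficients  # eta is in the column space
  mu <- exp(eta)
  # profile ML for the shape given the fitted means
  nu <- profileGammaShape(y, mu)
  ll <- gammaLoglik(y, mu, nu)
  methods::new("ModelFit", family = "gamma-log",
               coefficients = c(`(Intercept)` = unname(beta[1]),
                                x = unname(beta[2])),
               aux = nu, loglik = ll, converged = converged, n = n,
               trace = trace)
}

# one-dimensional profile MLE of the gamma shape on the log scale
profileGammaShape <- function(y, mu) {
  f <- function(logNu) gammaLoglik(y, mu, exp(logNu))
  opt <- stats::optimize(f, interval = c(-7, 15), maximum = TRUE,
                         tol = 1e-10)
  exp(opt$maximum)
}

# beta-regression log-likelihood; theta = (beta0, beta1, log phi)
betaLoglik <- function(theta, x, y) {
  mu <- stats::plogis(theta[1] + theta[2] * x)
  phi <- exp(theta[3])
  sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

#' Fit a beta regression (logit link, constant precision)
#'
#' Maximum likelihood for \eqn{y \sim Beta(\mu\phi, (1-\mu)\phi)} with
#' \eqn{\mu = logit^{-1}(\beta_0 + \beta_1 x)}. Newton ascent on
#' \eqn{(\beta, \log\phi)} using the analytic gradient and expected
#' (Fisher) information, with step halving so the log-likelihood never
#' decreases; \code{trace} stores the log-likelihood per accepted
#' iteration. Starting values: least squares on \code{logit(y)} for the
#' mean coefficients and the method-of-moments precision estimate.
#' Convergence: gradient max-norm < 1e-6.
#'
#' @param x predictor (metres of elevation SD); must not be constant.
#' @param y response strictly inside (0, 1); responses touching 0 or 1
#'   must first pass through [squeezeUnitInterval()].
#' @return A [ModelFit-class] with \code{family = "beta-logit"} and
#'   \code{aux} = precision \eqn{\phi}.
#' @examples
#' d <- generateResponseTable("beta-logit", -1, 0.02, 50, n = 200, seed = 1)
#' fitBetaRegression(d$x, d$y)
#' @export
fitBetaRegression <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(y)
  if (n < 3L) stop("at least 3 observations are required")
  if (any(y <= 0 | y >= 1))
    stop("beta regression requires y strictly inside (0, 1); ",
         "apply squeezeUnitInterval() first")
  if (stats::sd(x) == 0) {
    return(methods::new("ModelFit", family = "beta-logit",
                        coefficients = c(`(Intercept)` = NA_real_, x = NA_real_),
                        aux = NA_real_, loglik = NA_real_, converged = FALSE,
                        n = n, trace = numeric(0)))
  }
  X <- cbind(1, x)
  ystar <- stats::qlogis(y)
  ls <- stats::lm.fit(X, ystar)
  beta <- ls$coefficients
  muHat <- stats::plogis(drop(X %*% beta))
  # method-of-moments start for phi (Ferrari & Cribari-Neto 2004, eq. for
  # sigma^2 back-transformed through the link derivative)
  sig2 <- sum(ls$residuals^2) / (n - 2)
  phiTerms <- muHat * (1 - muHat) / (sig2 * (muHat * (1 - muHat))^2) - 1
  phi0 <- max(mean(phiTerms[is.finite(phiTerms)]), 0.5)
  theta <- c(beta, log(phi0))

  ll <- betaLoglik(theta, x, y)
  trace <- ll
  converged <- FALSE
  for (it in seq_len(200L)) {
    mu <- stats::plogis(theta[1] + theta[2] * x)
    phi <- exp(theta[3])
    dmu <- mu * (1 - mu)
    ys <- stats::qlogis(y)
    mus <- digamma(mu * phi) - digamma((1 - mu) * phi)
    gBeta <- phi * drop(crossprod(X, (ys - mus) * dmu))
    gPhi <- sum(mu * (ys - mus) + log(1 - y) -
                  digamma((1 - mu) * phi) + digamma(phi))
    grad <- c(gBeta, phi * gPhi)  # chain rule for log phi
    if (max(abs(grad)) < 1e-6) { converged <- TRUE; break }
    # expected information
    v <- trigamma(mu * phi) + trigamma((1 - mu) * phi)
    Kbb <- crossprod(X * (phi^2 * v * dmu^2), X)
    cvec <- phi * (trigamma(mu * phi) * mu - trigamma((1 - mu) * phi) * (1 - mu))
    Kbp <- drop(crossprod(X, dmu * cvec))
    Kpp <- sum(trigamma(mu * phi) * mu^2 +
                 trigamma((1 - mu) * phi) * (1 - mu)^2 - trigamma(phi))
    # information on the (beta, log phi) scale; E[score_phi] = 0, so the
    # log-phi reparametrization only multiplies by powers of phi
    K <- rbind(cbind(Kbb, phi * Kbp), c(phi * Kbp, phi^2 * Kpp))
    dir <- tryCatch(solve(K, grad), error = function(e) grad / max(abs(grad)))
    step <- 1
    repeat {
      cand <- theta + step * dir
      llNew <- betaLoglik(cand, x, y)
      if (is.finite(llNew) && llNew >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-10) { cand <- theta; llNew <- ll; break }
    }
    theta <- cand
    ll <- llNew
    trace <- c(trace, ll)
  }
  methods::new("ModelFit", family = "beta-logit",
               coefficients = c(`(Intercept)` = unname(theta[1]),
                                x = unname(theta[2])),
               aux = unname(exp(theta[3])), loglik = ll, converged = converged,
               n = n, trace = trace)
}

#' Compress [0, 1] data strictly into (0, 1)
#'
#' The Smithson-Verkuilen transform \eqn{y' = (y (n - 1) + 0.5) / n},
#' applied before beta regression whenever a beta-diversity value touches
#' 0 or 1. Order preserving, with 0.5 a fixed point.
#'
#' @param y values in [0, 1].
#' @param n sample size used for the compression (>= 2); by convention
#'   the replicate sample size.
#' @return values strictly inside (0, 1).
#' @examples
#' squeezeUnitInterval(c(0, 0.5, 1), 20)  # 0.025, 0.5, 0.975
#' @export
squeezeUnitInterval <- function(y, n = length(y)) {
  if (n < 2) stop("n must be >= 2")
  if (any(y < 0 | y > 1, na.rm = TRUE)) stop("y must lie in [0, 1]")
  (y * (n - 1) + 0.5) / n
}

#' @describeIn ModelFit Family label.
#' @param x a \code{ModelFit}.
#' @export
setMethod("modelFamily", "ModelFit", function(x) x@family)

#' @describeIn ModelFit Shape (gamma) or precision (beta) parameter.
#' @export
setMethod("modelAux", "ModelFit", function(x) x@aux)

#' @describeIn ModelFit Maximized log-likelihood.
#' @export
setMethod("logLikelihood", "ModelFit", function(x) x@loglik)

#' @describeIn ModelFit Convergence flag.
#' @export
setMethod("isConverged", "ModelFit", function(x) x@converged)

#' @export
setMethod("coef", "ModelFit", function(object) object@coefficients)

#' @describeIn ModelFit Fitted response mean at predictor values
#'   \code{x}.
#' @param object a \code{ModelFit}.
#' @export
setMethod("predictMean", "ModelFit", function(object, x) {
  eta <- object@coefficients[1] + object@coefficients[2] * x
  unname(if (object@family == "gamma-log") exp(eta) else stats::plogis(eta))
})

setMethod("show", "ModelFit", function(object) {
  cat("ModelFit [", object@family, "] n =", object@n,
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
  cat(sprintf("  beta0 = %.6g, beta1 = %.6g, %s = %.6g, logLik = %.4f\n",
              object@coefficients[1], object@coefficients[2],
              if (object@family == "gamma-log") "shape" else "precision",
              object@aux, object@loglik))
})

#' Standardized slope of a fitted relationship
#'
#' The increase in the response, in units of its standard deviation, per
#' 1 m increase in the standard deviation of elevation: the marginal
#' effect of the predictor on the response mean, evaluated at
#' \code{xRef}, divided by \code{sdY}. For the log link this is
#' \eqn{\beta_1 \hat\mu(x_{ref}) / sd_y}; for the logit link
#' \eqn{\beta_1 \hat\mu (1 - \hat\mu) / sd_y}. \code{xRef} is
#' conventionally the replicate mean of the predictor and \code{sdY} the
#' replicate sample SD of the (unsqueezed) response.
#'
#' @param fit a converged [ModelFit-class].
#' @param xRef reference predictor value (metres).
#' @param sdY sample SD of the response (> 0).
#' @return standardized slope (response SDs per metre), or
#'   \code{NA_real_} when \code{sdY} is 0 or the fit did not converge.
#' @export
standardizedSlope <- function(fit, xRef, sdY) {
  stopifnot(methods::is(fit, "ModelFit"))
  if (!fit@converged || !is.finite(sdY) || sdY <= 0) return(NA_real_)
  mu <- predictMean(fit, xRef)
  marginal <- if (fit@family == "gamma-log") fit@coefficients[2] * mu
  else fit@coefficients[2] * mu * (1 - mu)
  unname(marginal / sdY)
}

#' Pseudo-R-squared of a fitted relationship
#'
#' The original figure reports a median model R^2 without defining one
#' for non-Gaussian models, so a per-family convention is used: for the
#' gamma GLM, 1 - residual deviance / null deviance (the null model is
#' the intercept-only gamma GLM, whose fitted mean is the sample mean);
#' for beta regression, the squared Pearson correlation between the
#' link-scale fitted values and \code{logit(y)} (the Ferrari-Cribari-Neto
#' convention).
#'
#' @param fit a converged [ModelFit-class].
#' @param x,y the data the fit was computed on (for the beta family,
#'   \code{y} already squeezed).
#' @return value in [0, 1], or \code{NA_real_} for a degenerate null
#'   model or unconverged fit.
#' @export
pseudoR2 <- function(fit, x, y) {
  stopifnot(methods::is(fit, "ModelFit"))
  if (!fit@converged) return(NA_real_)
  if (fit@family == "gamma-log") {
    mu <- predictMean(fit, x)
    devNull <- gammaDeviance(y, mean(y))
    if (!is.finite(devNull) || devNull <= 0) return(NA_real_)
    max(0, min(1, 1 - gammaDeviance(y, mu) / devNull))
  } else {
    eta <- fit@coefficients[1] + fit@coefficients[2] * x
    if (stats::sd(eta) == 0 || stats::sd(stats::qlogis(y)) == 0)
      return(NA_real_)
    stats::cor(eta, stats::qlogis(y))^2
  }
}

#' Fit one replicate of the scaling regression
#'
#' Fits the per-form model of diversity on elevation SD for one
#' subsample replicate and derives the quantities the summaries consume:
#' the standardized slope (marginal effect at the replicate mean
#' predictor over the replicate response SD) and the pseudo-R^2. For the
#' beta form, responses touching 0 or 1 are squeezed with the replicate
#' sample size ([squeezeUnitInterval()]); the response SD used for
#' standardization is that of the unsqueezed values.
#'
#' @param x elevation SD values (metres), one per subsampled focal plot.
#' @param y diversity values (effective species numbers for alpha/gamma;
#'   mean dissimilarities in [0, 1] for beta).
#' @param form \code{"alpha"}, \code{"beta"} or \code{"gamma"}.
#' @return list with \code{fit} ([ModelFit-class]), \code{slope},
#'   \code{pseudoR2}, \code{xRef}, \code{sdY}, \code{squeezed} (flag).
#' @export
fitScalingReplicate <- function(x, y, form = c("alpha", "beta", "gamma")) {
  form <- match.arg(form)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(y) < 3L) stop("fewer than 3 usable observations in replicate")
  sdY <- stats::sd(y)
  squeezed <- FALSE
  if (form == "beta") {
    yFit <- y
    if (any(yFit <= 0 | yFit >= 1)) {
      yFit <- squeezeUnitInterval(yFit, length(yFit))
      squeezed <- TRUE
    }
    fit <- fitBetaRegression(x, yFit)
    r2 <- pseudoR2(fit, x, yFit)
  } else {
    fit <- fitGammaGLM(x, y)
    r2 <- pseudoR2(fit, x, y)
  }
  xRef <- mean(x)
  list(fit = fit, slope = standardizedSlope(fit, xRef, sdY),
       pseudoR2 = r2, xRef = xRef, sdY = sdY, squeezed = squeezed)
}

#' Summarize replicate fits at one radius and form
#'
#' Percentiles (2.5, 25, 50, 75, 97.5; linear-interpolation convention)
#' of the standardized slopes over converged replicate fits, the median
#' pseudo-R^2, and a pointwise prediction band: the 2.5th/97.5th (and
#' median) percentiles over replicates of the fitted mean response on
#' \code{xGrid}. Non-converged replicates (or replicates with missing
#' slopes) are counted and excluded.
#'
#' @param replicateFits list of [fitScalingReplicate()] results.
#' @param xGrid predictor grid for the prediction band.
#' @param radiusKm,form labels carried into the summary.
#' @return list of class \code{"ScalingSummary"}: \code{radiusKm},
#'   \code{form}, \code{slopePercentiles} (named numeric(5)),
#'   \code{medianPseudoR2}, \code{band} (data.frame x, lower, median,
#'   upper), \code{nReplicatesUsed}, \code{nReplicatesFailed}.
#' @export
summarizeReplicates <- function(replicateFits, xGrid, radiusKm = NA_real_,
                                form = NA_character_) {
  ok <- vapply(replicateFits, function(r)
    isTRUE(r$fit@converged) && is.finite(r$slope), logical(1))
  if (!any(ok))
    stop("no converged replicate fits to summarize",
         if (!is.na(radiusKm)) paste0(" (radius ", radiusKm, " km, ",
                                      form, ")"))
  slopes <- vapply(replicateFits[ok], `[[`, numeric(1), "slope")
  r2s <- vapply(replicateFits[ok], `[[`, numeric(1), "pseudoR2")
  probs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  sp <- stats::quantile(slopes, probs, type = 7, names = TRUE)
  pred <- vapply(replicateFits[ok], function(r)
    predictMean(r$fit, xGrid), numeric(length(xGrid)))
  pred <- matrix(pred, nrow = length(xGrid))
  band <- data.frame(
    x = xGrid,
    lower = apply(pred, 1L, stats::quantile, probs = 0.025, type = 7),
    median = apply(pred, 1L, stats::quantile, probs = 0.5, type = 7),
    upper = apply(pred, 1L, stats::quantile, probs = 0.975, type = 7))
  structure(list(
    radiusKm = radiusKm, form = form,
    slopePercentiles = sp,
    medianPseudoR2 = stats::median(r2s, na.rm = TRUE),
    band = band,
    nReplicatesUsed = sum(ok),
    nReplicatesFailed = sum(!ok)),
    class = "ScalingSummary")
}

#' @exportS3Method base::print
print.ScalingSummary <- function(x, ...) {
  cat("ScalingSummary:", x$form, "diversity at", x$radiusKm, "km\n")
  cat("  standardized slope percentiles:\n")
  print(signif(x$slopePercentiles, 4))
  cat(sprintf("  median pseudo-R2 = %.4f over %d replicates (%d failed)\n",
              x$medianPseudoR2, x$nReplicatesUsed, x$nReplicatesFailed))
  invisible(x)
}
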