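#' @include plot-communities.R
NULL

#' Effective species number (Hill number of order 1)
#'
#' The exponential of Shannon entropy of relative abundances,
#' \eqn{D = \exp(-\sum_i p_i \ln p_i)}: the number of equally abundant
#' species that would give the same entropy. Abundance-weighted, base
#' invariant, and bounded by 1 and the number of species with positive
#' abundance. Zero abundances contribute nothing.
#'
#' @param abundances non-negative numeric vector of basal areas (or any
#'   abundance currency); at least one value must be positive.
#' @return effective species number (>= 1).
#' @examples
#' effectiveSpeciesNumber(c(1, 1, 1, 1))   # 4
#' effectiveSpeciesNumber(c(0.7, 0.3))     # 1.842...
#' @export
effectiveSpeciesNumber <- function(abundances) {
  a <- abundances[abundances > 0]
  if (anyNA(abundances) || any(abundances < 0))
    stop("abundances must be non-negative and non-missing")
  if (!length(a)) stop("at least one abundance must be positive")
  p <- a / sum(a)
  exp(-sum(p * log(p)))
}

# per-plot effective species numbers for all columns of a sparse matrix
plotEffectiveSpeciesNumbers <- function(a) {
  tot <- Matrix::colSums(a)
  if (any(tot <= 0)) stop("every plot must have positive total abundance")
  h <- numeric(ncol(a))
  df <- Matrix::summary(a)
  p <- df$x / tot[df$j]
  contrib <- -p * log(p)
  h <- vapply(split(contrib, factor(df$j, levels = seq_len(ncol(a)))),
              sum, numeric(1))
  exp(unname(h))
}

#' Alpha diversity of a neighbourhood
#'
#' The median of the per-plot effective species numbers of all plots in
#' the neighbourhood (focal plot included). For an even plot count the
#' median is the mean of the two central values.
#'
#' @param neighborhood a [PlotCommunitySet-class] holding the member
#'   plots of one circular neighbourhood.
#' @return median effective species number.
#' @export
alphaDiversity <- function(neighborhood) {
  stopifnot(methods::is(neighborhood, "PlotCommunitySet"))
  if (nPlots(neighborhood) < 1L) stop("neighborhood has no member plots")
  stats::median(plotEffectiveSpeciesNumbers(abundanceMatrix(neighborhood)))
}

#' Bray-Curtis dissimilarity between two communities
#'
#' \eqn{d = 1 - 2 \sum_i \min(a_i, b_i) / (\sum_i a_i + \sum_i b_i)} on
#' basal areas: 0 for identical abundance vectors, 1 for disjoint
#' species sets, symmetric. With \code{proportions = TRUE} each vector is
#' first divided by its total, removing between-plot abundance weighting
#' (both readings of "abundance-weighted dissimilarity" are defensible;
#' raw basal areas are the default).
#'
#' @param a,b non-negative abundance vectors over the same species index
#'   (names are matched when both are named); totals must be positive.
#' @param proportions compare within-plot proportions instead of raw
#'   basal areas.
#' @return dissimilarity in [0, 1].
#' @examples
#' pairwiseDissimilarity(c(A = 2, B = 1), c(A = 1, B = 2))  # 1/3
#' @export
pairwiseDissimilarity <- function(a, b, proportions = FALSE) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    sp <- union(names(a), names(b))
    a <- stats::setNames(ifelse(is.na(match(sp, names(a))), 0,
                                a[match(sp, names(a))]), sp)
    b <- stats::setNames(ifelse(is.na(match(sp, names(b))), 0,
                                b[match(sp, names(b))]), sp)
  }
  if (length(a) != length(b))
    stop("abundance vectors must cover the same species index")
  sa <- sum(a); sb <- sum(b)
  if (!isTRUE(sa > 0) || !isTRUE(sb > 0))
    stop("both communities must have positive total abundance")
  if (proportions) { a <- a / sa; b <- b / sb; sa <- sb <- 1 }
  1 - 2 * sum(pmin(a, b)) / (sa + sb)
}

#' Beta diversity of a neighbourhood
#'
#' Mean pairwise Bray-Curtis dissimilarity over all unordered pairs of
#' member plots (focal included). Undefined — \code{NA} — for a
#' single-plot neighbourhood, since no pair exists.
#'
#' @inheritParams alphaDiversity
#' @param proportions see [pairwiseDissimilarity()].
#' @return mean dissimilarity in [0, 1], or \code{NA_real_} when the
#'   neighbourhood holds a single plot.
#' @export
betaDiversity <- function(neighborhood, proportions = FALSE) {
  stopifnot(methods::is(neighborhood, "PlotCommunitySet"))
  m <- nPlots(neighborhood)
  if (m < 1L) stop("neighborhood has no member plots")
  if (m == 1L) return(NA_real_)
  a <- as.matrix(abundanceMatrix(neighborhood))
  if (proportions) a <- sweep(a, 2L, colSums(a), "/")
  tot <- colSums(a)
  d <- 0
  for (i in seq_len(m - 1L)) {
    ai <- a[, i]
    for (j in (i + 1L):m) {
      d <- d + 1 - 2 * sum(pmin(ai, a[, j])) / (tot[i] + tot[j])
    }
  }
  unname(d / (m * (m - 1L) / 2L))
}

#' Gamma diversity of a neighbourhood
#'
#' Basal areas are summed species-wise across all member plots (focal
#' included) and the pooled vector's effective species number is
#' returned: the total aggregated diversity of the neighbourhood treated
#' as a single community.
#'
#' @inheritParams alphaDiversity
#' @return pooled effective species number.
#' @export
gammaDiversity <- function(neighborhood) {
  stopifnot(methods::is(neighborhood, "PlotCommunitySet"))
  if (nPlots(neighborhood) < 1L) stop("neighborhood has no member plots")
  pooled <- Matrix::rowSums(abundanceMatrix(neighborhood))
  effectiveSpeciesNumber(pooled)
}
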