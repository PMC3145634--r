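#' Monte-Carlo approximation of a cost-integrated metric
#'
#' Reformulates the cost integral as an expectation over the random cost C
#' and approximates it by the empirical average of the metric at n i.i.d.
#' sampled costs. By the Strong Law of Large Numbers the estimate converges
#' almost surely to \code{\link{integrateExact}}; the Monte-Carlo standard
#' error (sample standard deviation of the draws divided by sqrt(n))
#' quantifies the accuracy, and by the CLT the estimate is asymptotically
#' normal around the exact value. Sampling is plain i.i.d. with replacement —
#' no variance reduction — matching the estimator whose standard error is
#' reported.
#'
#' Since the metric value at a grid level is deterministic, repeated draws of
#' the same level reuse a single evaluation; the estimator is unchanged.
#'
#' @param net a \linkS4class{WeightedNetwork}.
#' @param metric as in \code{\link{integrateExact}}.
#' @param dist a \linkS4class{CostDistribution}.
#' @param n number of samples (>= 2, so the standard error is defined).
#' @param seed integer RNG seed (mandatory; recorded in the result).
#' @return an \linkS4class{MCEstimate}.
#' @examples
#' net <- randomWeightedNetwork(10, seed = 1)
#' dist <- uniformCostDistribution(costGrid(10))
#' est <- mcIntegrate(net, "globalEfficiency", dist, n = 200, seed = 7)
#' confidenceBand(est)
#' @export
mcIntegrate <- function(net, metric, dist, n, seed) {
  stopifnot(is(net, "WeightedNetwork"), is(dist, "CostDistribution"))
  if (dist@grid@nNodes != net@nNodes) {
    stop("distribution grid and network node counts differ")
  }
  n <- as.integer(n)
  if (is.na(n) || n < 2L) {
    stop("'n' must be at least 2 (the MC standard error is undefined for ",
         "a single sample)")
  }
  if (missing(seed)) stop("'seed' is required")
  seed <- as.integer(seed)
  costs <- sampleCosts(dist, n, seed)
  ks <- .costToK(costs, net@nNodes, nullOk = dist@grid@nullIncluded)
  uk <- sort(unique(ks))
  uvals <- .metricValuesAtK(net, uk, metric)
  values <- uvals[match(ks, uk)]
  est <- mean(values)
  se <- stats::sd(values) / sqrt(n)
  new("MCEstimate",
      estimate = est,
      standardError = se,
      nSamples = n,
      values = values,
      runningMean = cumsum(values) / seq_len(n),
      seed = seed)
}

#' Confidence band around a Monte-Carlo estimate
#'
#' estimate +/- multiplier * MC standard error. The default multiplier 2
#' gives the usual approximate 95\% band under asymptotic normality.
#'
#' @param est an \linkS4class{MCEstimate}.
#' @param multiplier positive band half-width in standard-error units.
#' @return named numeric vector \code{c(lower, upper)}.
#' @export
confidenceBand <- function(est, multiplier = 2) {
  stopifnot(is(est, "MCEstimate"))
  if (!is.finite(multiplier) || multiplier <= 0) {
    stop("'multiplier' must be positive")
  }
  c(lower = est@estimate - multiplier * est@standardError,
    upper = est@estimate + multiplier * est@standardError)
}

#' Running-mean convergence trace of a Monte-Carlo estimate
#'
#' Per-sample cumulative mean and cumulative standard error, for convergence
#' plots of the running mean plus or minus twice the running standard error.
#' The standard error at the first sample is undefined and reported as NA.
#'
#' @param est an \linkS4class{MCEstimate}.
#' @return a data.frame with columns \code{index}, \code{runningMean},
#'   \code{runningSE}; the last row reproduces the estimate and its standard
#'   error.
#' @export
runningTrace <- function(est) {
  stopifnot(is(est, "MCEstimate"))
  x <- est@values
  idx <- seq_along(x)
  s1 <- cumsum(x)
  s2 <- cumsum(x^2)
  rmean <- s1 / idx
  # cumulative sample variance; guard tiny negative rounding
  rvar <- pmax(s2 - s1^2 / idx, 0) / (idx - 1)
  rse <- sqrt(rvar / idx)
  rse[1L] <- NA_real_
  data.frame(index = idx, runningMean = rmean, runningSE = rse)
}
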