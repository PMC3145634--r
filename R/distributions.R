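#' Uniform distribution over a cost grid
#'
#' Equal mass 1/M at every grid level — the choice when no cost regime is to
#' be favored a priori.
#'
#' @param grid a \linkS4class{CostGrid}.
#' @return a \linkS4class{CostDistribution}.
#' @export
uniformCostDistribution <- function(grid) {
  stopifnot(is(grid, "CostGrid"))
  m <- length(grid@levels)
  new("CostDistribution", grid = grid, pmf = rep(1 / m, m),
      family = "uniform", parameters = list())
}

#' Beta-binomial distribution over a cost grid
#'
#' Weights the grid level with k edges (k = 1..M) by the Beta-binomial mass
#' at x = k - 1 with M - 1 trials:
#' P(x) = C(M-1, x) * B(x + alpha, M - 1 - x + beta) / B(alpha, beta).
#' The unit shift restricts the support to the M levels of the grid, which
#' excludes the null cost. Choosing alpha = beta > 1 de-emphasizes the
#' extremes of the cost range; alpha = beta = 1 recovers the uniform
#' distribution exactly. Asymmetric parameters are permitted. Masses are
#' evaluated in log space (log-gamma) and renormalized once, so grids with
#' thousands of levels do not underflow.
#'
#' @param grid a \linkS4class{CostGrid}(without the null cost).
#' @param alpha,beta positive shape parameters.
#' @return a \linkS4class{CostDistribution}.
#' @examples
#' pmf(betaBinomialCostDistribution(costGrid(3), 2, 2)) # 0.3, 0.4, 0.3
#' @export
betaBinomialCostDistribution <- function(grid, alpha, beta) {
  stopifnot(is(grid, "CostGrid"))
  if (grid@nullIncluded) {
    stop("the Beta-binomial pmf is defined on the standard grid without ",
         "the null cost")
  }
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0) {
    stop("'alpha' and 'beta' must be positive")
  }
  m <- length(grid@levels)
  x <- seq_len(m) - 1  # number of edges minus one
  logp <- lchoose(m - 1, x) + lbeta(x + alpha, m - 1 - x + beta) -
    lbeta(alpha, beta)
  p <- exp(logp - max(logp))
  new("CostDistribution", grid = grid, pmf = p / sum(p),
      family = "betabinomial", parameters = list(alpha = alpha, beta = beta))
}

#' Point mass at a single grid cost
#'
#' Cost-integration against a point mass evaluates the metric at that single
#' level; provided as the degenerate case of interval restriction.
#'
#' @param grid a \linkS4class{CostGrid}.
#' @param cost a grid level.
#' @return a \linkS4class{CostDistribution}.
#' @export
pointMassCostDistribution <- function(grid, cost) {
  stopifnot(is(grid, "CostGrid"))
  sel <- .levelsInInterval(grid@levels, cost, cost, "closed")
  if (!any(sel)) stop("'cost' is not on the grid")
  p <- as.numeric(sel) / sum(sel)
  new("CostDistribution", grid = grid, pmf = p,
      family = "pointmass", parameters = list(cost = cost))
}

#' Restrict a cost distribution to an interval of grid levels
#'
#' Zeroes the pmf outside the chosen interval and renormalizes, yielding the
#' conditional distribution given that the cost falls in the interval. Because
#' the support is discrete, the result depends on whether the endpoints are
#' included: \code{closure} selects the closed interval [lower, upper]
#' (default), the left-half-open (lower, upper], or the right-half-open
#' [lower, upper). Conclusions drawn from a restricted integration are
#' conditional on this choice of subset, so the bounds and closure are kept in
#' the descriptor.
#'
#' @param dist a \linkS4class{CostDistribution}.
#' @param lower,upper grid levels with lower <= upper.
#' @param closure one of \code{"closed"}, \code{"left_half_open"},
#'   \code{"right_half_open"}.
#' @return a \linkS4class{CostDistribution} supported on the interval.
#' @export
restrictToInterval <- function(dist, lower, upper,
                               closure = c("closed", "left_half_open",
                                           "right_half_open")) {
  stopifnot(is(dist, "CostDistribution"))
  closure <- match.arg(closure)
  if (lower > upper) stop("'lower' must not exceed 'upper'")
  .costToK(c(lower, upper), dist@grid@nNodes,
           nullOk = dist@grid@nullIncluded)  # bounds must be on the grid
  sel <- .levelsInInterval(dist@grid@levels, lower, upper, closure)
  p <- dist@pmf
  p[!sel] <- 0
  if (sum(p) <= 0) {
    stop("restriction leaves no support (empty interval or zero mass)")
  }
  params <- dist@parameters
  params$lower <- lower
  params$upper <- upper
  params$closure <- closure
  new("CostDistribution", grid = dist@grid, pmf = p / sum(p),
      family = dist@family, parameters = params)
}

#' Sample costs from a cost distribution
#'
#' \code{n} independent draws with replacement from the pmf; the seed is
#' mandatory so every stochastic estimate is reproducible.
#'
#' @param dist a \linkS4class{CostDistribution}.
#' @param n number of draws (>= 1).
#' @param seed integer RNG seed.
#' @return numeric vector of n grid levels.
#' @export
sampleCosts <- function(dist, n, seed) {
  stopifnot(is(dist, "CostDistribution"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  if (missing(seed)) stop("'seed' is required")
  set.seed(as.integer(seed))
  sample(dist@grid@levels, n, replace = TRUE, prob = dist@pmf)
}

# Tolerance-robust membership of grid levels in an interval.
.levelsInInterval <- function(levels, lower, upper, closure, tol = 1e-9) {
  switch(closure,
    closed = levels >= lower - tol & levels <= upper + tol,
    left_half_open = levels > lower + tol & levels <= upper + tol,
    right_half_open = levels >= lower - tol & levels < upper - tol
  )
}
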