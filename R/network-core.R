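#' Construct and validate a WeightedNetwork
#'
#' Validates a square association matrix and returns a
#' \linkS4class{WeightedNetwork}. Asymmetry within \code{tolerance}
#' (relative to the largest absolute entry) is repaired by averaging with the
#' transpose; larger asymmetry is an error. The diagonal is always forced to
#' zero: the cost and topology of a weighted network depend only on the
#' off-diagonal entries. The standardized flag is TRUE iff every off-diagonal
#' weight lies in [0, 1].
#'
#' @param weights numeric N x N matrix, N >= 2, all entries finite.
#' @param tolerance relative symmetry tolerance (default 1e-8).
#' @param standardization character label recording how the weights were
#'   standardized; informational only.
#' @return a \linkS4class{WeightedNetwork}.
#' @examples
#' w <- matrix(0, 3, 3)
#' w[upper.tri(w)] <- c(0.9, 0.5, 0.1)
#' net <- weightedNetwork(w + t(w))
#' isStandardized(net)
#' @export
weightedNetwork <- function(weights, tolerance = 1e-8, standardization = "none") {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop("'weights' must be a numeric matrix")
  }
  if (nrow(weights) != ncol(weights)) stop("'weights' must be square")
  n <- nrow(weights)
  if (n < 2L) stop("a network needs at least 2 nodes")
  if (!all(is.finite(weights))) stop("'weights' must be finite")
  scale <- max(1, max(abs(weights)))
  asym <- max(abs(weights - t(weights)))
  if (asym > tolerance * scale) {
    stop(sprintf("matrix is asymmetric beyond tolerance (max |w - t(w)| = %g)",
                 asym))
  }
  w <- (weights + t(weights)) / 2
  diag(w) <- 0
  off <- w[upper.tri(w)]
  new("WeightedNetwork",
      nNodes = as.integer(n),
      weights = w,
      standardized = all(off >= 0 & off <= 1),
      standardization = standardization)
}

#' Construct a BinaryGraph from an adjacency matrix
#'
#' @param adjacency square symmetric matrix with entries in {0, 1}; the
#'   diagonal is zeroed.
#' @return a \linkS4class{BinaryGraph}.
#' @export
binaryGraph <- function(adjacency) {
  if (!is.matrix(adjacency)) stop("'adjacency' must be a matrix")
  a <- adjacency
  storage.mode(a) <- "integer"
  diag(a) <- 0L
  new("BinaryGraph", nNodes = as.integer(nrow(a)), adjacency = a)
}

#' Standardize a correlation matrix to unit-interval weights
#'
#' Maps correlations in [-1, 1] to association weights in [0, 1], turning
#' negative correlations into positive measures of association. Two maps are
#' offered: \code{"absolute"} (w = |r|, the default) and \code{"affine"}
#' (w = (r + 1)/2). The two maps order the weights differently when negative
#' correlations are present (|r| is not monotone on [-1, 1]), so rank-based
#' results can depend on this choice; the chosen method is recorded in the
#' returned object so it can be reported alongside any result.
#'
#' @param correlations numeric N x N correlation matrix, entries in [-1, 1].
#' @param method \code{"absolute"} or \code{"affine"}.
#' @param tolerance symmetry tolerance passed to \code{\link{weightedNetwork}}.
#' @return a standardized \linkS4class{WeightedNetwork}.
#' @examples
#' r <- diag(3)
#' r[upper.tri(r)] <- c(-0.8, 0, 1); r[lower.tri(r)] <- t(r)[lower.tri(r)]
#' weightMatrix(standardizeCorrelations(r)) # |r| off the diagonal
#' @export
standardizeCorrelations <- function(correlations,
                                    method = c("absolute", "affine"),
                                    tolerance = 1e-8) {
  method <- match.arg(method)
  if (!is.matrix(correlations) || !is.numeric(correlations)) {
    stop("'correlations' must be a numeric matrix")
  }
  if (any(!is.finite(correlations)) ||
      any(correlations < -1) || any(correlations > 1)) {
    stop("correlations must be finite and lie in [-1, 1]")
  }
  w <- switch(method,
    absolute = abs(correlations),
    affine = (correlations + 1) / 2
  )
  diag(w) <- 0
  weightedNetwork(w, tolerance = tolerance, standardization = method)
}

#' Weighted cost (connectivity strength) of a network
#'
#' The weighted cost of a standardized network is the mean of its N(N-1)
#' off-diagonal weights (equivalently, the mean of the M upper-triangle
#' weights). It generalizes the edge density of an unweighted graph, with the
#' saturated weighted graph (all unit weights) attaining cost 1, and is used
#' interchangeably with the phrase connectivity strength.
#'
#' @param net a standardized \linkS4class{WeightedNetwork}.
#' @return numeric in [0, 1].
#' @examples
#' w <- matrix(0, 3, 3); w[upper.tri(w)] <- c(0.9, 0.5, 0.1)
#' weightedCost(weightedNetwork(w + t(w))) # 0.5
#' @export
weightedCost <- function(net) {
  stopifnot(is(net, "WeightedNetwork"))
  if (!net@standardized) {
    stop("weighted cost requires weights standardized to [0, 1]")
  }
  mean(net@weights[upper.tri(net@weights)])
}

#' Cost (edge density) of an unweighted graph
#'
#' The number of edges divided by the saturated count M = N(N-1)/2.
#'
#' @param graph a \linkS4class{BinaryGraph}.
#' @return numeric in [0, 1].
#' @export
binaryCost <- function(graph) {
  stopifnot(is(graph, "BinaryGraph"))
  n <- graph@nNodes
  m <- n * (n - 1L) / 2
  edgeCount(graph) / m
}

#' The discrete cost grid of an N-node network
#'
#' Returns the ordered set of achievable costs {k/M : k = 1..M} with
#' M = N(N-1)/2. The null cost is excluded by default since an edgeless graph
#' carries no topology; set \code{includeNull = TRUE} only for diagnostics
#' (e.g. to demonstrate the effect of its exclusion on the integrated value).
#'
#' @param nNodes integer >= 2.
#' @param includeNull logical; retain the level 0 (default FALSE).
#' @return a \linkS4class{CostGrid}.
#' @examples
#' costLevels(costGrid(3)) # 1/3, 2/3, 1
#' costLevels(costGrid(2)) # just 1
#' @export
costGrid <- function(nNodes, includeNull = FALSE) {
  nNodes <- as.integer(nNodes)
  if (is.na(nNodes) || nNodes < 2L) stop("'nNodes' must be an integer >= 2")
  m <- nNodes * (nNodes - 1L) / 2
  levels <- seq_len(m) / m
  if (includeNull) levels <- c(0, levels)
  new("CostGrid", nNodes = nNodes, levels = levels,
      nullIncluded = isTRUE(includeNull))
}

## Internal helpers -----------------------------------------------------------

# Upper-triangle node pairs in lexicographic (i, j) order, i < j.
# which(lower.tri(.), arr.ind) enumerates (i > j) column by column, which is
# exactly lexicographic order of the transposed pairs (j, i).
.pairIndex <- function(n) {
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  cbind(i = idx[, 2L], j = idx[, 1L])
}

# Upper-triangle weights in lexicographic pair order.
.pairWeights <- function(w, pairs) {
  w[cbind(pairs[, 1L], pairs[, 2L])]
}

# Map a cost to its grid index k, rejecting off-grid values.
.costToK <- function(cost, nNodes, nullOk = FALSE, tol = 1e-9) {
  m <- nNodes * (nNodes - 1L) / 2
  k <- round(cost * m)
  if (any(abs(cost - k / m) > tol) || any(k > m) ||
      any(k < if (nullOk) 0 else 1)) {
    stop("cost is not on the grid {k/M}; off-grid costs are not rounded")
  }
  as.integer(k)
}
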