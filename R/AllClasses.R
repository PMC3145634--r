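#' @import methods
NULL

#' WeightedNetwork: a symmetric association matrix with zero diagonal
#'
#' Container for a weighted undirected graph given by its association matrix.
#' The diagonal is always zero (self-association does not enter cost or
#' topology) and the matrix is exactly symmetric after construction. The
#' \code{standardized} flag records whether every off-diagonal weight lies in
#' the unit interval, which is required by \code{\link{weightedCost}} and
#' \code{\link{weightedEfficiency}} but not by rank-based operations
#' (thresholding and cost-integration depend only on the ordering of the
#' weights).
#'
#' @slot nNodes integer, number of vertices (at least 2).
#' @slot weights numeric N x N matrix of association weights.
#' @slot standardized logical, TRUE iff all off-diagonal weights are in [0, 1].
#' @slot standardization character, how the weights were standardized
#'   (\code{"none"}, \code{"absolute"} or \code{"affine"}).
#'
#' @seealso \code{\link{weightedNetwork}}, \code{\link{standardizeCorrelations}}
#' @export
setClass("WeightedNetwork",
  representation(
    nNodes = "integer",
    weights = "matrix",
    standardized = "logical",
    standardization = "character"
  )
)

setValidity("WeightedNetwork", function(object) {
  w <- object@weights
  n <- object@nNodes
  if (!is.numeric(w)) return("weights must be numeric")
  if (nrow(w) != n || ncol(w) != n) return("weights must be an nNodes x nNodes matrix")
  if (n < 2L) return("a network needs at least 2 nodes")
  if (!all(is.finite(w))) return("weights must be finite")
  if (!isTRUE(all.equal(w, t(w), tolerance = 0))) return("weights must be exactly symmetric")
  if (any(diag(w) != 0)) return("diagonal must be zero")
  std <- all(w[upper.tri(w)] >= 0 & w[upper.tri(w)] <= 1)
  if (object@standardized != std) return("standardized flag inconsistent with weights")
  TRUE
})

#' BinaryGraph: a symmetric 0/1 adjacency matrix
#'
#' Result of thresholding a \linkS4class{WeightedNetwork} at a grid cost, or
#' any unweighted undirected graph of interest. Edge count is bounded by
#' M = N(N-1)/2.
#'
#' @slot nNodes integer number of vertices.
#' @slot adjacency integer N x N matrix with entries in {0, 1}, zero diagonal.
#'
#' @seealso \code{\link{binaryGraph}}, \code{\link{thresholdAtCost}}
#' @export
setClass("BinaryGraph",
  representation(nNodes = "integer", adjacency = "matrix")
)

setValidity("BinaryGraph", function(object) {
  a <- object@adjacency
  n <- object@nNodes
  if (nrow(a) != n || ncol(a) != n) return("adjacency must be nNodes x nNodes")
  if (n < 1L) return("nNodes must be positive")
  if (!all(a %in% c(0L, 1L))) return("adjacency entries must be 0 or 1")
  if (any(a != t(a))) return("adjacency must be symmetric")
  if (any(diag(a) != 0L)) return("diagonal must be zero")
  TRUE
})

#' CostGrid: the achievable costs of a thresholded network
#'
#' The ordered support {k/M : k = 1..M} with M = N(N-1)/2, i.e. every wiring
#' cost attainable by keeping the top-k ranked edges of an N-node network. The
#' null cost is excluded by default: an edgeless graph carries no topology and
#' including it would only deflate cost-integrated metrics (see the two-node
#' worked example in the vignette). A grid with the null cost retained can be
#' requested explicitly for diagnostic purposes.
#'
#' @slot nNodes integer number of vertices.
#' @slot levels numeric vector of grid costs, strictly increasing, ending at 1.
#' @slot nullIncluded logical, TRUE if the level 0 was retained.
#'
#' @seealso \code{\link{costGrid}}
#' @export
setClass("CostGrid",
  representation(nNodes = "integer", levels = "numeric", nullIncluded = "logical")
)

setValidity("CostGrid", function(object) {
  n <- object@nNodes
  if (n < 2L) return("nNodes must be at least 2")
  m <- n * (n - 1L) / 2
  expected <- (seq_len(m)) / m
  if (object@nullIncluded) expected <- c(0, expected)
  if (length(object@levels) != length(expected)) return("wrong number of grid levels")
  if (!isTRUE(all.equal(object@levels, expected, tolerance = 0))) {
    return("levels must be {k/M}, k = 1..M (optionally preceded by 0)")
  }
  TRUE
})

#' CostDistribution: a probability mass function over a CostGrid
#'
#' Holds the pmf used to weight cost levels during cost-integration, together
#' with a descriptor (family and parameters) sufficient to reproduce it.
#'
#' @slot grid a \linkS4class{CostGrid}.
#' @slot pmf numeric vector aligned with \code{levels(grid)}, non-negative,
#'   summing to 1 within 1e-12.
#' @slot family character family name (\code{"uniform"}, \code{"betabinomial"},
#'   or \code{"pointmass"}).
#' @slot parameters named list of family parameters (alpha, beta, interval
#'   bounds, closure, ...).
#'
#' @seealso \code{\link{uniformCostDistribution}},
#'   \code{\link{betaBinomialCostDistribution}},
#'   \code{\link{restrictToInterval}}
#' @export
setClass("CostDistribution",
  representation(
    grid = "CostGrid",
    pmf = "numeric",
    family = "character",
    parameters = "list"
  )
)

setValidity("CostDistribution", function(object) {
  if (length(object@pmf) != length(object@grid@levels)) {
    return("pmf must align with the grid levels")
  }
  if (any(object@pmf < 0)) return("pmf must be non-negative")
  if (abs(sum(object@pmf) - 1) > 1e-12) return("pmf must sum to 1 within 1e-12")
  TRUE
})

#' RankMatrix: edge ranks and percentile ranks of a weighted network
#'
#' The M upper-triangle weights are ranked without ties (rank 1 = largest
#' weight by default); ties in the weights are broken by the lexicographic
#' order of the index pairs (i, j), never randomly, since random allocation
#' would inject spurious random topology into the thresholded graphs.
#' Percentile ranks are rank/M exactly.
#'
#' @slot nNodes integer number of vertices.
#' @slot ranks integer N x N symmetric matrix, off-diagonal entries a
#'   permutation of 1..M on the upper triangle.
#' @slot percentile numeric N x N symmetric matrix equal to ranks/M.
#' @slot decreasing logical; TRUE when rank 1 is the largest weight.
#'
#' @seealso \code{\link{edgeRanks}}
#' @export
setClass("RankMatrix",
  representation(
    nNodes = "integer",
    ranks = "matrix",
    percentile = "matrix",
    decreasing = "logical"
  )
)

setValidity("RankMatrix", function(object) {
  n <- object@nNodes
  m <- n * (n - 1L) / 2
  r <- object@ranks[upper.tri(object@ranks)]
  if (!setequal(r, seq_len(m))) return("upper-triangle ranks must be a permutation of 1..M")
  if (any(object@ranks != t(object@ranks))) return("rank matrix must be symmetric")
  if (max(abs(object@percentile - object@ranks / m)) != 0) {
    return("percentile must equal ranks/M exactly")
  }
  TRUE
})

#' MCEstimate: a Monte-Carlo estimate of a cost-integrated metric
#'
#' Point estimate with its Monte-Carlo standard error (sample standard
#' deviation of the metric draws divided by sqrt(n)) and the running-mean
#' trace used for convergence diagnostics.
#'
#' @slot estimate numeric point estimate (the empirical average).
#' @slot standardError numeric non-negative MC standard error.
#' @slot nSamples integer number of draws.
#' @slot values numeric metric value at each draw.
#' @slot runningMean numeric cumulative means, last element equals estimate.
#' @slot seed integer seed used for the draws.
#'
#' @seealso \code{\link{mcIntegrate}}, \code{\link{confidenceBand}},
#'   \code{\link{runningTrace}}
#' @export
setClass("MCEstimate",
  representation(
    estimate = "numeric",
    standardError = "numeric",
    nSamples = "integer",
    values = "numeric",
    runningMean = "numeric",
    seed = "integer"
  )
)

setValidity("MCEstimate", function(object) {
  if (object@nSamples < 2L) return("nSamples must be at least 2")
  if (length(object@runningMean) != object@nSamples) {
    return("runningMean must have one entry per sample")
  }
  if (abs(object@runningMean[object@nSamples] - object@estimate) > 1e-12) {
    return("last running mean must equal the estimate")
  }
  if (object@standardError < 0) return("standardError must be non-negative")
  TRUE
})

#' LayerSpec: a layered topology prescription over the cost grid
#'
#' Partitions the cost range (0, 1] into bands, each tagged with a target
#' topology ("regular" for a ring-lattice ordering, "random" for seeded
#' uniform draws among unused node pairs). Used by
#' \code{\link{layeredAssociationMatrix}} to build association matrices whose
#' thresholded graphs follow the requested pattern band by band.
#'
#' @slot boundaries numeric ascending grid costs, last element 1; band b covers
#'   grid costs in (boundaries[b-1], boundaries[b]].
#' @slot topologies character one tag per band, "regular" or "random".
#' @slot seed integer seed for the random bands.
#'
#' @seealso \code{\link{layerSpec}}, \code{\link{layeredAssociationMatrix}}
#' @export
setClass("LayerSpec",
  representation(boundaries = "numeric", topologies = "character", seed = "integer")
)

setValidity("LayerSpec", function(object) {
  b <- object@boundaries
  if (length(b) < 1L) return("at least one band is required")
  if (is.unsorted(b, strictly = TRUE)) return("boundaries must be strictly increasing")
  if (b[length(b)] != 1) return("boundaries must end at 1")
  if (any(b <= 0)) return("boundaries must be positive")
  if (length(object@topologies) != length(b)) return("one topology tag per band")
  if (!all(object@topologies %in% c("regular", "random"))) {
    return("topologies must be 'regular' or 'random'")
  }
  TRUE
})

## show methods ---------------------------------------------------------------

setMethod("show", "WeightedNetwork", function(object) {
  cat("WeightedNetwork with", object@nNodes, "nodes\n")
  cat("  standardized:", object@standardized,
      sprintf("(%s)", object@standardization), "\n")
  w <- object@weights[upper.tri(object@weights)]
  cat(sprintf("  weight range: [%.4g, %.4g]\n", min(w), max(w)))
})

setMethod("show", "BinaryGraph", function(object) {
  n <- object@nNodes
  ne <- sum(object@adjacency[upper.tri(object@adjacency)])
  m <- n * (n - 1L) / 2
  cat("BinaryGraph with", n, "nodes and", ne, "edges",
      sprintf("(cost %.4g)\n", ne / m))
})

setMethod("show", "CostGrid", function(object) {
  cat("CostGrid for", object@nNodes, "nodes:", length(object@levels), "levels",
      if (object@nullIncluded) "(null cost included)" else "", "\n")
})

setMethod("show", "CostDistribution", function(object) {
  cat("CostDistribution (", object@family, ") over ",
      length(object@grid@levels), " levels\n", sep = "")
  p <- object@parameters
  if (length(p)) {
    cat("  parameters:",
        paste(names(p), vapply(p, function(x) paste(format(x), collapse = ","),
                               character(1)),
              sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "MCEstimate", function(object) {
  cat(sprintf("MCEstimate: %.6g (MC standard error %.3g, n = %d, seed = %d)\n",
              object@estimate, object@standardError, object@nSamples,
              object@seed))
})

setMethod("show", "LayerSpec", function(object) {
  cat("LayerSpec:", paste(sprintf("%s up to %.3g", object@topologies,
                                  object@boundaries), collapse = "; "),
      "| seed", object@seed, "\n")
})
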