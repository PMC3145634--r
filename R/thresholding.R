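#' Edge ranks and percentile ranks of a weighted network
#'
#' Ranks the M upper-triangle weights (rank 1 = largest weight when
#' \code{decreasing = TRUE}, the default). Tied weights are resolved by the
#' lexicographic order of their index pairs (i, j) — a deterministic rule;
#' random tie-breaking would inject a spurious amount of random topology into
#' the thresholded graphs. Percentile ranks are rank/M exactly, so
#' thresholding at grid cost c keeps precisely the c*M top-ranked edges.
#'
#' Rank-based operations accept any finite symmetric matrix, standardized or
#' not, because ranks are invariant under strictly monotone increasing
#' transformations of the weights. For a monotone decreasing transformation
#' the order reverses; rank the transformed network with
#' \code{decreasing = FALSE} to recover the original ranks.
#'
#' @param net a \linkS4class{WeightedNetwork}.
#' @param decreasing logical; rank largest weight first (default TRUE).
#' @return a \linkS4class{RankMatrix}.
#' @examples
#' w <- matrix(0, 3, 3); w[upper.tri(w)] <- c(0.9, 0.5, 0.1)
#' edgeRanks(weightedNetwork(w + t(w)))@ranks
#' @export
edgeRanks <- function(net, decreasing = TRUE) {
  stopifnot(is(net, "WeightedNetwork"))
  n <- net@nNodes
  m <- n * (n - 1L) / 2
  pairs <- .pairIndex(n)
  w <- .pairWeights(net@weights, pairs)
  # stable radix sort: ties keep lexicographic pair order
  ord <- order(if (decreasing) -w else w, method = "radix")
  ranks <- integer(m)
  ranks[ord] <- seq_len(m)
  rmat <- matrix(0L, n, n)
  rmat[cbind(pairs[, 1L], pairs[, 2L])] <- ranks
  rmat <- rmat + t(rmat)
  new("RankMatrix", nNodes = n, ranks = rmat, percentile = rmat / m,
      decreasing = isTRUE(decreasing))
}

#' Count tied ranks among the edge weights
#'
#' Number of upper-triangle weights sharing their value with at least one
#' other weight. A data-quality diagnostic: cost-integration relies on ranks,
#' and networks that differ markedly in their number of tied ranks are
#' contaminated by an artificial level of deterministic (here: index-order)
#' topology at the tied levels.
#'
#' @param net a \linkS4class{WeightedNetwork}.
#' @return integer count of weights involved in ties (0 when all distinct).
#' @export
countTiedRanks <- function(net) {
  stopifnot(is(net, "WeightedNetwork"))
  w <- net@weights[upper.tri(net@weights)]
  tab <- table(w)
  as.integer(sum(tab[tab > 1L]))
}

#' Threshold a weighted network at a prescribed cost
#'
#' The thresholding function tau: keeps edge (i, j) iff its percentile rank is
#' at most \code{cost}, producing an unweighted graph whose cost equals
#' \code{cost} exactly. Off-grid costs are rejected, not rounded — exactness of
#' the resulting edge count is part of the contract.
#'
#' @param net a \linkS4class{WeightedNetwork}.
#' @param cost a level of \code{costGrid(nNodes(net))} (0 is admitted only
#'   when \code{grid} includes the null cost).
#' @param grid optional \linkS4class{CostGrid} defining admissible costs;
#'   defaults to the standard grid without the null cost.
#' @return a \linkS4class{BinaryGraph} with exactly cost*M edges.
#' @examples
#' w <- matrix(0, 3, 3); w[upper.tri(w)] <- c(0.9, 0.5, 0.1)
#' net <- weightedNetwork(w + t(w))
#' binaryCost(thresholdAtCost(net, 1/3)) # exactly 1/3
#' @export
thresholdAtCost <- function(net, cost, grid = costGrid(nNodes(net))) {
  stopifnot(is(net, "WeightedNetwork"), is(grid, "CostGrid"))
  if (grid@nNodes != net@nNodes) stop("grid and network sizes differ")
  k <- .costToK(cost, net@nNodes, nullOk = grid@nullIncluded)
  rk <- edgeRanks(net)
  .graphAtK(rk, k)
}

#' Nested thresholded graphs along a cost profile
#'
#' Thresholds once per requested cost, reusing a single ranking so that the
#' graphs are nested: the edge set at cost c_k is contained in the edge set at
#' any larger cost.
#'
#' @param net a \linkS4class{WeightedNetwork}.
#' @param costs ascending vector of grid levels.
#' @return list of \linkS4class{BinaryGraph} objects, one per cost.
#' @export
thresholdProfile <- function(net, costs) {
  stopifnot(is(net, "WeightedNetwork"))
  if (is.unsorted(costs, strictly = TRUE)) {
    stop("'costs' must be strictly ascending")
  }
  ks <- .costToK(costs, net@nNodes)
  rk <- edgeRanks(net)
  lapply(ks, function(k) .graphAtK(rk, k))
}

# Binary graph keeping ranks <= k.
.graphAtK <- function(rankMatrix, k) {
  adj <- (rankMatrix@ranks >= 1L & rankMatrix@ranks <= k)
  storage.mode(adj) <- "integer"
  diag(adj) <- 0L
  new("BinaryGraph", nNodes = rankMatrix@nNodes, adjacency = adj)
}
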