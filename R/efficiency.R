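#' Shortest-path (hop) distance matrix of an unweighted graph
#'
#' Breadth-first hop distances between all node pairs. Disconnected pairs are
#' reported as \code{Inf}; their reciprocal contributes exactly 0 to the
#' efficiency metrics, so every metric below is well defined for disconnected
#' graphs.
#'
#' @param graph a \linkS4class{BinaryGraph}.
#' @return numeric N x N matrix of hop counts, zero diagonal, \code{Inf} for
#'   unreachable pairs.
#' @export
shortestPathMatrix <- function(graph) {
  stopifnot(is(graph, "BinaryGraph"))
  g <- igraph::graph_from_adjacency_matrix(graph@adjacency, mode = "undirected")
  d <- igraph::distances(g)
  dimnames(d) <- NULL
  d
}

#' Global efficiency of an unweighted graph
#'
#' The average over ordered node pairs of the reciprocal shortest-path
#' length: E(G) = (1/(N(N-1))) * sum_{i != j} 1/d_ij, with 1/Inf taken as 0
#' for disconnected pairs. Normalized to [0, 1]: 1 for the complete graph, 0
#' for the empty one. Unlike the characteristic path length it remains finite
#' on disconnected graphs, which makes it integrable over the full cost range.
#'
#' @param graph a \linkS4class{BinaryGraph}.
#' @return numeric in [0, 1].
#' @examples
#' path3 <- binaryGraph(rbind(c(0,1,0), c(1,0,1), c(0,1,0)))
#' globalEfficiency(path3) # 5/6
#' @export
globalEfficiency <- function(graph) {
  stopifnot(is(graph, "BinaryGraph"))
  .globalEfficiencyAdj(graph@adjacency)
}

#' Local efficiency of an unweighted graph
#'
#' The mean over nodes of the global efficiency of the subgraph induced by
#' each node's neighbors. Nodes with fewer than two neighbors contribute 0
#' (an isolated node, or a neighbor subgraph with no pairs, has no local
#' structure to score), which keeps the metric defined at every cost level.
#'
#' @param graph a \linkS4class{BinaryGraph}.
#' @return numeric in [0, 1].
#' @export
localEfficiency <- function(graph) {
  stopifnot(is(graph, "BinaryGraph"))
  adj <- graph@adjacency
  n <- graph@nNodes
  tot <- 0
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0L)
    if (length(nb) >= 2L) {
      tot <- tot + .globalEfficiencyAdj(adj[nb, nb, drop = FALSE])
    }
  }
  tot / n
}

#' Weighted shortest-path matrix
#'
#' Shortest paths where each edge (i, j) has length phi(w_ij) for a monotone
#' decreasing map phi from (0, 1] to [1, Inf); with the default reciprocal
#' map every edge length is at least 1, so all weighted distances are at
#' least 1 and the weighted efficiency below is bounded by 1. Requires a
#' standardized, fully weighted network (all off-diagonal weights strictly
#' positive): a zero weight would have infinite length under the reciprocal
#' map and is rejected.
#'
#' @param net a standardized \linkS4class{WeightedNetwork} with strictly
#'   positive off-diagonal weights.
#' @param phi elementwise edge-length map; default \code{function(w) 1/w}.
#' @return numeric N x N matrix of weighted path lengths.
#' @export
weightedShortestPathMatrix <- function(net, phi = function(w) 1 / w) {
  stopifnot(is(net, "WeightedNetwork"))
  if (!net@standardized) {
    stop("weighted shortest paths require weights standardized to [0, 1]")
  }
  w <- net@weights
  if (any(w[upper.tri(w)] <= 0)) {
    stop("weighted shortest paths require strictly positive weights; ",
         "zero-weight pairs make the network non-fully weighted")
  }
  len <- phi(w)
  diag(len) <- 0
  if (any(len[upper.tri(len)] <= 0) || any(!is.finite(len[upper.tri(len)]))) {
    stop("'phi' must map the weights to finite, strictly positive lengths")
  }
  g <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                           weighted = TRUE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(d) <- NULL
  d
}

#' Weighted efficiency of a standardized network
#'
#' The efficiency computed on weighted shortest paths:
#' E_w = (1/(N(N-1))) * sum_{i != j} 1/d^w_ij. With the reciprocal length map
#' every d^w_ij >= 1, so E_w lies in [0, 1]. Whenever every direct edge is
#' itself a weighted shortest path — guaranteed when
#' max(W) <= 2 * min(W) — the weighted efficiency collapses to the weighted
#' cost exactly, which is why this metric is generally a poor substitute for
#' a genuine topology measure.
#'
#' @inheritParams weightedShortestPathMatrix
#' @return numeric in [0, 1] (for the default phi).
#' @examples
#' w <- matrix(0, 3, 3); w[upper.tri(w)] <- c(1, 0.4, 1)
#' weightedEfficiency(weightedNetwork(w + t(w))) # 5/6
#' @export
weightedEfficiency <- function(net, phi = function(w) 1 / w) {
  d <- weightedShortestPathMatrix(net, phi)
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

## Internal kernels -----------------------------------------------------------

# Global efficiency of a plain adjacency matrix, Floyd-Warshall distances.
# Small dense graphs (neighbor subgraphs, desk-scale networks) are the hot
# path here; igraph's per-call overhead dominates at that size.
.globalEfficiencyAdj <- function(adj) {
  n <- nrow(adj)
  if (n < 2L) return(0)
  d <- .apspAdj(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# All-pairs shortest hop counts by vectorized Floyd-Warshall.
.apspAdj <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0L, 1, Inf)
  diag(d) <- 0
  for (v in seq_len(n)) {
    cand <- outer(d[, v], d[v, ], "+")
    upd <- cand < d
    if (any(upd)) d[upd] <- cand[upd]
  }
  d
}
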