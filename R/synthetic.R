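#' Random fully weighted network
#'
#' I.i.d. off-diagonal weights drawn uniformly from the open unit interval,
#' symmetrized; with probability one all weights are distinct, so the edge
#' ranking has no ties. The workhorse fixture for property tests.
#'
#' @param nNodes integer >= 2.
#' @param seed integer RNG seed (mandatory: generators are deterministic).
#' @return a standardized \linkS4class{WeightedNetwork}.
#' @export
randomWeightedNetwork <- function(nNodes, seed) {
  nNodes <- as.integer(nNodes)
  if (is.na(nNodes) || nNodes < 2L) stop("'nNodes' must be an integer >= 2")
  if (missing(seed)) stop("'seed' is required")
  set.seed(as.integer(seed))
  m <- nNodes * (nNodes - 1L) / 2
  w <- matrix(0, nNodes, nNodes)
  w[upper.tri(w)] <- stats::runif(m)
  weightedNetwork(w + t(w))
}

#' A pair of proportional networks
#'
#' Returns the base network together with a copy whose association matrix is
#' scaled by \code{factor}. The pair has weighted costs in exact ratio
#' \code{factor} but identical edge ranks, hence identical threshold profiles
#' and identical cost-integrated metrics under every distribution — the
#' canonical illustration that cost-integration is blind to differences in
#' connectivity strength, while thresholding both at a fixed absolute cutoff
#' conflates the two.
#'
#' @param base a standardized \linkS4class{WeightedNetwork}.
#' @param factor scalar in the open interval (0, 1).
#' @return list with elements \code{base} and \code{scaled}.
#' @export
proportionalPair <- function(base, factor) {
  stopifnot(is(base, "WeightedNetwork"))
  if (!base@standardized) stop("'base' must be standardized")
  if (!is.finite(factor) || factor <= 0 || factor >= 1) {
    stop("'factor' must lie in the open interval (0, 1)")
  }
  list(base = base, scaled = weightedNetwork(factor * base@weights))
}

#' A pair of two-node networks
#'
#' Two networks on two nodes with single off-diagonal weights w1 and w2. The
#' cost grid of a two-node network has the single level 1 (the null cost is
#' excluded), so both networks attain uniformly cost-integrated global
#' efficiency exactly 1 regardless of how w1 and w2 compare — the worked
#' example motivating the exclusion of the null cost, whose inclusion would
#' drag both values down to 1/2.
#'
#' @param w1,w2 weights in the open interval (0, 1).
#' @return list of two standardized \linkS4class{WeightedNetwork}s.
#' @export
twoNodePair <- function(w1, w2) {
  for (w in c(w1, w2)) {
    if (!is.finite(w) || w <= 0 || w >= 1) {
      stop("weights must lie in the open interval (0, 1)")
    }
  }
  mk <- function(w) weightedNetwork(matrix(c(0, w, w, 0), 2, 2))
  list(first = mk(w1), second = mk(w2))
}

#' Ring-lattice edge ordering, truncated to a rank band
#'
#' Deterministic regular ordering of all M node pairs: increasing ring
#' distance min(|i - j|, N - |i - j|), ties by lexicographic pair index. The
#' first N edges form the ring itself; the full range saturates the graph.
#' Used as the "regular" layer pattern of
#' \code{\link{layeredAssociationMatrix}}, in the conventional ring-lattice
#' (small-world substrate) sense.
#'
#' @param nNodes integer >= 2.
#' @param kStart,kEnd rank band, 1 <= kStart <= kEnd <= M.
#' @return integer matrix with columns \code{i}, \code{j}, one row per edge
#'   rank in the band.
#' @export
latticeBandEdges <- function(nNodes, kStart, kEnd) {
  nNodes <- as.integer(nNodes)
  if (is.na(nNodes) || nNodes < 2L) stop("'nNodes' must be an integer >= 2")
  m <- nNodes * (nNodes - 1L) / 2
  kStart <- as.integer(kStart)
  kEnd <- as.integer(kEnd)
  if (kStart < 1L || kEnd > m || kStart > kEnd) {
    stop("rank band must satisfy 1 <= kStart <= kEnd <= M")
  }
  pairs <- .pairIndex(nNodes)
  ringDist <- pmin(pairs[, 2L] - pairs[, 1L],
                   nNodes - (pairs[, 2L] - pairs[, 1L]))
  ord <- order(ringDist, pairs[, 1L], pairs[, 2L])
  pairs[ord[kStart:kEnd], , drop = FALSE]
}

#' Construct a LayerSpec
#'
#' @param boundaries ascending grid costs ending at 1; band b spans the grid
#'   levels in (boundaries[b-1], boundaries[b]].
#' @param topologies character vector, one of "regular"/"random" per band.
#' @param seed integer seed used by the random bands.
#' @return a \linkS4class{LayerSpec}.
#' @export
layerSpec <- function(boundaries, topologies, seed) {
  if (missing(seed)) stop("'seed' is required")
  new("LayerSpec", boundaries = as.numeric(boundaries),
      topologies = as.character(topologies), seed = as.integer(seed))
}

#' Layered association matrix with cost-dependent topology
#'
#' Builds a weighted network whose thresholded graph at any grid cost c in
#' band b consists exactly of the band patterns laid down so far: "regular"
#' bands follow the ring-lattice ordering (restricted to still-unused pairs),
#' "random" bands draw their pairs uniformly without replacement from the
#' unused pairs (seeded). Strictly decreasing weights are then assigned in
#' rank order, so the construction has no tied ranks. Any strictly decreasing
#' weight assignment consistent with the target rank order yields the same
#' thresholded graphs — rank invariance used constructively.
#'
#' Two specs that agree on their leading bands produce matrices whose
#' thresholded graphs are identical at every cost level inside the shared
#' bands, while e.g. a hybrid regular/random/regular matrix is strictly more
#' globally efficient than an all-regular one when integrated over the full
#' grid, its random layers acting as shortcuts.
#'
#' @param nNodes integer >= 2.
#' @param spec a \linkS4class{LayerSpec}.
#' @return a standardized \linkS4class{WeightedNetwork}.
#' @examples
#' reg <- layeredAssociationMatrix(30, layerSpec(1, "regular", seed = 1))
#' hyb <- layeredAssociationMatrix(
#'   30, layerSpec(c(1/3, 2/3, 1), c("regular", "random", "regular"), seed = 1))
#' @export
layeredAssociationMatrix <- function(nNodes, spec) {
  stopifnot(is(spec, "LayerSpec"))
  nNodes <- as.integer(nNodes)
  if (is.na(nNodes) || nNodes < 2L) stop("'nNodes' must be an integer >= 2")
  m <- nNodes * (nNodes - 1L) / 2
  bounds <- .costToK(spec@boundaries, nNodes)
  pairs <- .pairIndex(nNodes)
  # pair id of (i, j), i < j, in lexicographic order
  latticePairs <- latticeBandEdges(nNodes, 1L, m)
  latticeIds <- .pairId(latticePairs[, 1L], latticePairs[, 2L], nNodes)
  used <- logical(m)
  orderIds <- integer(m)
  set.seed(spec@seed)
  kPrev <- 0L
  for (b in seq_along(bounds)) {
    size <- bounds[b] - kPrev
    if (size < 1L) stop("band ", b, " is empty")
    ids <- if (spec@topologies[b] == "regular") {
      avail <- latticeIds[!used[latticeIds]]
      avail[seq_len(size)]
    } else {
      avail <- which(!used)
      if (length(avail) < size) stop("random band cannot be filled")
      avail[sample.int(length(avail), size)]
    }
    orderIds[(kPrev + 1L):bounds[b]] <- ids
    used[ids] <- TRUE
    kPrev <- bounds[b]
  }
  # strictly decreasing weights in rank order, all inside (0, 1)
  w <- matrix(0, nNodes, nNodes)
  sel <- cbind(pairs[orderIds, 1L], pairs[orderIds, 2L])
  w[sel] <- 1 - (seq_len(m) - 0.5) / m
  weightedNetwork(w + t(w))
}

# Lexicographic pair id of (i, j) with i < j.
.pairId <- function(i, j, n) {
  (i - 1L) * n - i * (i + 1L) / 2 + j
}
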