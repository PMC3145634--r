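#' Number of nodes of a network object
#'
#' @param x a \linkS4class{WeightedNetwork}, \linkS4class{BinaryGraph} or
#'   \linkS4class{CostGrid}.
#' @return integer node count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname nNodes
#' @export
setMethod("nNodes", "WeightedNetwork", function(x) x@nNodes)

#' @rdname nNodes
#' @export
setMethod("nNodes", "BinaryGraph", function(x) x@nNodes)

#' @rdname nNodes
#' @export
setMethod("nNodes", "CostGrid", function(x) x@nNodes)

#' Association weight matrix of a WeightedNetwork
#'
#' @param x a \linkS4class{WeightedNetwork}.
#' @return the numeric N x N weight matrix.
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @rdname weightMatrix
#' @export
setMethod("weightMatrix", "WeightedNetwork", function(x) x@weights)

#' Is the network standardized to the unit interval?
#'
#' @param x a \linkS4class{WeightedNetwork}.
#' @return logical; TRUE iff every off-diagonal weight lies in [0, 1].
#' @export
setGeneric("isStandardized", function(x) standardGeneric("isStandardized"))

#' @rdname isStandardized
#' @export
setMethod("isStandardized", "WeightedNetwork", function(x) x@standardized)

#' Adjacency matrix of a BinaryGraph
#'
#' @param x a \linkS4class{BinaryGraph}.
#' @return the integer N x N adjacency matrix.
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname adjacencyMatrix
#' @export
setMethod("adjacencyMatrix", "BinaryGraph", function(x) x@adjacency)

#' Number of edges of a BinaryGraph
#'
#' @param x a \linkS4class{BinaryGraph}.
#' @return integer edge count.
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname edgeCount
#' @export
setMethod("edgeCount", "BinaryGraph", function(x) {
  as.integer(sum(x@adjacency[upper.tri(x@adjacency)]))
})

#' Grid levels of a CostGrid or CostDistribution
#'
#' @param x a \linkS4class{CostGrid} or \linkS4class{CostDistribution}.
#' @return numeric vector of cost levels.
#' @export
setGeneric("costLevels", function(x) standardGeneric("costLevels"))

#' @rdname costLevels
#' @export
setMethod("costLevels", "CostGrid", function(x) x@levels)

#' @rdname costLevels
#' @export
setMethod("costLevels", "CostDistribution", function(x) x@grid@levels)

#' Probability mass function of a CostDistribution
#'
#' @param x a \linkS4class{CostDistribution}.
#' @return numeric vector of probabilities aligned with \code{costLevels(x)}.
#' @export
setGeneric("pmf", function(x) standardGeneric("pmf"))

#' @rdname pmf
#' @export
setMethod("pmf", "CostDistribution", function(x) x@pmf)
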