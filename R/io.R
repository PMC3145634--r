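#' Read a dense association matrix from delimited text
#'
#' Headerless N x N matrix, comma- or tab/whitespace-delimited (auto-detected).
#'
#' @param path file path.
#' @param tolerance symmetry tolerance passed to \code{\link{weightedNetwork}}.
#' @return a \linkS4class{WeightedNetwork}.
#' @export
readAssociationMatrix <- function(path, tolerance = 1e-8) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = sep))
  dimnames(m) <- NULL
  weightedNetwork(m, tolerance = tolerance)
}

#' Write a dense association matrix as delimited text
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces the matrix to full double precision.
#'
#' @param x a \linkS4class{WeightedNetwork} or numeric matrix.
#' @param path output file path.
#' @param sep column delimiter (default comma).
#' @return invisibly, \code{path}.
#' @export
writeAssociationMatrix <- function(x, path, sep = ",") {
  w <- if (is(x, "WeightedNetwork")) x@weights else x
  lines <- apply(w, 1L, function(row) {
    paste(sprintf("%.17g", row), collapse = sep)
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read a weighted edge list
#'
#' Three columns (node_i, node_j, weight) with 0-based node indices, each
#' undirected pair listed once. Pairs absent from the file get weight 0.
#'
#' @param path file path.
#' @param nNodes optional node count; defaults to 1 + the largest index seen.
#' @param tolerance symmetry tolerance passed to \code{\link{weightedNetwork}}.
#' @return a \linkS4class{WeightedNetwork}.
#' @export
readEdgeList <- function(path, nNodes = NULL, tolerance = 1e-8) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  e <- utils::read.table(path, header = FALSE, sep = sep)
  if (ncol(e) != 3L) stop("an edge list needs exactly 3 columns")
  i <- as.integer(e[[1L]]) + 1L
  j <- as.integer(e[[2L]]) + 1L
  if (any(i == j)) stop("self-loops are not allowed")
  n <- if (is.null(nNodes)) max(i, j) else as.integer(nNodes)
  w <- matrix(0, n, n)
  w[cbind(i, j)] <- e[[3L]]
  w[cbind(j, i)] <- e[[3L]]
  weightedNetwork(w, tolerance = tolerance)
}

#' Write a weighted edge list
#'
#' All N(N-1)/2 undirected pairs, 0-based indices, full double precision.
#'
#' @param net a \linkS4class{WeightedNetwork}.
#' @param path output file path.
#' @param sep column delimiter (default tab).
#' @return invisibly, \code{path}.
#' @export
writeEdgeList <- function(net, path, sep = "\t") {
  stopifnot(is(net, "WeightedNetwork"))
  pairs <- .pairIndex(net@nNodes)
  w <- .pairWeights(net@weights, pairs)
  lines <- sprintf("%d%s%d%s%.17g",
                   pairs[, 1L] - 1L, sep, pairs[, 2L] - 1L, sep, w)
  writeLines(lines, path)
  invisible(path)
}
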