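# Independent oracles and small fixture builders.

# Symmetric matrix from its upper-triangle values (column-major upper.tri
# order, i.e. (1,2), (1,3), (2,3), (1,4), ...).
symFromUpper <- function(n, up) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- up
  m + t(m)
}

# Exhaustive shortest-path oracle: enumerate every simple path between each
# ordered pair by depth-first search. Tractable for n <= 7; independent of
# both igraph and the package's distance kernels.
# `lengths` is a matrix of edge lengths (1 for hop counting); entries with
# length 0 off the diagonal mean "no edge".
bruteDistances <- function(lengths) {
  n <- nrow(lengths)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  dfs <- function(v, target, visited, acc) {
    if (v == target) {
      d[cbind(1, 1)] # no-op, keep scoping obvious
      return(acc)
    }
    best <- Inf
    for (u in seq_len(n)) {
      if (!visited[u] && lengths[v, u] > 0) {
        visited[u] <- TRUE
        best <- min(best, dfs(u, target, visited, acc + lengths[v, u]))
        visited[u] <- FALSE
      }
    }
    best
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        visited <- logical(n)
        visited[i] <- TRUE
        d[i, j] <- dfs(i, j, visited, 0)
      }
    }
  }
  d
}

# Efficiency from an arbitrary distance matrix.
efficiencyFromDistances <- function(d) {
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# Random adjacency matrix with edge probability p.
randomAdjacency <- function(n, p) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  a + t(a)
}
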