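test_that("shortestPathMatrix gives hop counts with Inf for unreachable", {
  path3 <- binaryGraph(symFromUpper(3, c(1, 0, 1)))
  d <- shortestPathMatrix(path3)
  expect_equal(d[1, 3], 2)
  expect_equal(diag(d), rep(0, 3))
  expect_true(all(is.infinite(shortestPathMatrix(
    binaryGraph(matrix(0, 4, 4)))[upper.tri(diag(4))])))
  expect_true(all(shortestPathMatrix(binaryGraph(1 - diag(5)))[upper.tri(diag(5))] == 1))
})

test_that("global efficiency matches hand-derived values", {
  expect_equal(globalEfficiency(binaryGraph(1 - diag(6))), 1)
  expect_equal(globalEfficiency(binaryGraph(matrix(0, 6, 6))), 0)
  expect_equal(globalEfficiency(binaryGraph(symFromUpper(3, c(1, 0, 1)))), 5 / 6)
})

test_that("local efficiency follows the neighbor-subgraph convention", {
  expect_equal(localEfficiency(binaryGraph(1 - diag(4))), 1)
  expect_equal(localEfficiency(binaryGraph(matrix(0, 4, 4))), 0)
  # star on 4 nodes: hub's neighbors are mutually unconnected, leaves have a
  # single neighbor
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- 1
  expect_equal(localEfficiency(binaryGraph(star + t(star))), 0)
  # triangle plus pendant: hand enumeration
  a <- symFromUpper(4, c(1, 1, 1, 0, 0, 1))
  # nodes 1,2,3 form a triangle; node 4 attached to 3. Node 3's neighbor
  # subgraph {1,2,4} has the single edge (1,2): efficiency 2/6.
  expect_equal(localEfficiency(binaryGraph(a)), (1 + 1 + 1 / 3 + 0) / 4)
})

test_that("distances agree with exhaustive path enumeration on small graphs", {
  set.seed(77)
  for (rep in 1:12) {
    n <- sample(4:7, 1)
    adj <- randomAdjacency(n, p = stats::runif(1, 0.2, 0.8))
    g <- binaryGraph(adj)
    expect_equal(shortestPathMatrix(g), bruteDistances(adj))
    expect_equal(globalEfficiency(g), efficiencyFromDistances(bruteDistances(adj)))
    expect_equal(localEfficiency(g), {
      tot <- 0
      for (i in seq_len(n)) {
        nb <- which(adj[i, ] > 0)
        if (length(nb) >= 2) {
          tot <- tot + efficiencyFromDistances(
            bruteDistances(adj[nb, nb, drop = FALSE]))
        }
      }
      tot / n
    })
  }
})

test_that("weighted shortest paths use inverse-weight edge lengths", {
  # all unit weights: saturated unit-length graph
  d <- weightedShortestPathMatrix(weightedNetwork(symFromUpper(3, c(1, 1, 1))))
  expect_true(all(d[upper.tri(d)] == 1))
  # detour beats a weak direct edge: 2 < 1/0.4
  net <- weightedNetwork(symFromUpper(3, c(1, 0.4, 1)))
  expect_equal(weightedShortestPathMatrix(net)[1, 3], 2)
  # weights in [0.5, 1]: the direct edge always wins
  set.seed(5)
  w <- symFromUpper(6, stats::runif(15, 0.5, 1))
  dnet <- weightedNetwork(w)
  dd <- weightedShortestPathMatrix(dnet)
  expect_equal(dd[upper.tri(dd)], (1 / w)[upper.tri(w)])
  # zero weights rejected under the reciprocal map
  expect_error(weightedShortestPathMatrix(
    weightedNetwork(symFromUpper(3, c(0.5, 0, 0.5)))), "positive")
})

test_that("weighted distances agree with exhaustive enumeration", {
  set.seed(21)
  for (rep in 1:6) {
    n <- sample(4:6, 1)
    w <- symFromUpper(n, stats::runif(n * (n - 1) / 2, 0.05, 1))
    net <- weightedNetwork(w)
    lens <- 1 / w
    diag(lens) <- 0
    expect_equal(weightedShortestPathMatrix(net), bruteDistances(lens))
  }
})

test_that("weighted efficiency matches hand enumeration and the collapse regime", {
  expect_equal(weightedEfficiency(weightedNetwork(symFromUpper(4, rep(1, 6)))), 1)
  expect_equal(weightedEfficiency(weightedNetwork(symFromUpper(3, c(1, 0.4, 1)))),
               5 / 6)
  # max <= 2 * min: every direct edge is a weighted shortest path, so the
  # weighted efficiency collapses to the weighted cost
  set.seed(8)
  w <- symFromUpper(10, stats::runif(45, 0.5, 1))
  net <- weightedNetwork(w)
  expect_equal(weightedEfficiency(net), weightedCost(net), tolerance = 1e-14)
})

test_that("efficiencies are bounded and monotone in cost", {
  net <- randomWeightedNetwork(15, seed = 6)
  cv <- efficiencyCurve(net, "globalEfficiency")
  expect_true(all(cv$value >= 0 & cv$value <= 1))
  expect_true(all(diff(cv$value) >= 0))
  expect_equal(cv$value[nrow(cv)], 1) # saturated graph
  cvl <- efficiencyCurve(net, "localEfficiency")
  expect_true(all(cvl$value >= 0 & cvl$value <= 1))
  expect_equal(cvl$value[nrow(cvl)], 1)
})
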