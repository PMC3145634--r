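test_that("edgeRanks orders weights descending with index tie-breaking", {
  net <- weightedNetwork(symFromUpper(3, c(0.9, 0.5, 0.1)))
  rk <- edgeRanks(net)
  expect_identical(rk@ranks[1, 2], 1L)
  expect_identical(rk@ranks[1, 3], 2L)
  expect_identical(rk@ranks[2, 3], 3L)
  expect_equal(rk@percentile, rk@ranks / 3)
  expect_identical(rk@ranks, t(rk@ranks))

  # all-tied weights: ranks follow lexicographic (i, j) order
  tied <- edgeRanks(weightedNetwork(symFromUpper(3, rep(0.5, 3))))
  expect_identical(tied@ranks[1, 2], 1L)
  expect_identical(tied@ranks[1, 3], 2L)
  expect_identical(tied@ranks[2, 3], 3L)
})

test_that("ranks are invariant under strictly increasing transforms", {
  net <- randomWeightedNetwork(15, seed = 11)
  w <- weightMatrix(net)
  for (f in list(function(x) x^2, sqrt, function(x) 0.5 + 0.5 * x, exp)) {
    tw <- f(w)
    diag(tw) <- 0
    expect_identical(edgeRanks(weightedNetwork(tw))@ranks, edgeRanks(net)@ranks)
  }
  # decreasing transform reverses the order; ascending ranking recovers it
  dec <- 1 - 0.5 * w
  diag(dec) <- 0
  expect_identical(edgeRanks(weightedNetwork(dec), decreasing = FALSE)@ranks,
                   edgeRanks(net)@ranks)
})

test_that("countTiedRanks counts weights involved in ties", {
  expect_identical(countTiedRanks(randomWeightedNetwork(10, seed = 5)), 0L)
  expect_identical(countTiedRanks(weightedNetwork(symFromUpper(3, rep(0.5, 3)))), 3L)
  up <- c(0.1, 0.1, 0.2, 0.3, 0.4, 0.4, 0.5, 0.6, 0.7, 0.8)
  expect_identical(countTiedRanks(weightedNetwork(symFromUpper(5, up))), 4L)
})

test_that("thresholdAtCost keeps exactly the top-ranked edges", {
  net <- weightedNetwork(symFromUpper(3, c(0.9, 0.5, 0.1)))
  g <- thresholdAtCost(net, 1 / 3)
  expect_identical(adjacencyMatrix(g)[1, 2], 1L)
  expect_identical(edgeCount(g), 1L)
  expect_identical(edgeCount(thresholdAtCost(net, 1)), 3L)

  # tied weights follow the index rule
  tied <- weightedNetwork(symFromUpper(3, rep(0.4, 3)))
  g2 <- thresholdAtCost(tied, 2 / 3)
  expect_identical(adjacencyMatrix(g2)[1, 2], 1L)
  expect_identical(adjacencyMatrix(g2)[1, 3], 1L)
  expect_identical(adjacencyMatrix(g2)[2, 3], 0L)

  # off-grid costs are rejected, not rounded
  expect_error(thresholdAtCost(net, 0.5), "not on the grid")
  expect_error(thresholdAtCost(net, 0), "not on the grid")
})

test_that("thresholding achieves the requested cost exactly on the grid", {
  for (n in c(3, 10, 30)) {
    net <- randomWeightedNetwork(n, seed = n)
    for (cost in costLevels(costGrid(n))) {
      expect_identical(binaryCost(thresholdAtCost(net, cost)), cost)
    }
  }
})

test_that("threshold profiles are nested", {
  net <- randomWeightedNetwork(8, seed = 2)
  costs <- costLevels(costGrid(8))
  graphs <- thresholdProfile(net, costs)
  expect_length(graphs, length(costs))
  for (k in seq_len(length(graphs) - 1)) {
    a <- adjacencyMatrix(graphs[[k]])
    b <- adjacencyMatrix(graphs[[k + 1]])
    expect_true(all(b[a == 1L] == 1L))
    expect_identical(sum(b) - sum(a), 2L) # one extra undirected edge
  }
  expect_error(thresholdProfile(net, rev(costs)[1:2]), "ascending")
  single <- thresholdProfile(net, costs[5])
  expect_identical(adjacencyMatrix(single[[1]]),
                   adjacencyMatrix(thresholdAtCost(net, costs[5])))
})

test_that("proportional matrices have identical threshold profiles", {
  pair <- proportionalPair(randomWeightedNetwork(12, seed = 9), 0.5)
  costs <- costLevels(costGrid(12))
  pa <- thresholdProfile(pair$base, costs)
  pb <- thresholdProfile(pair$scaled, costs)
  for (k in seq_along(costs)) {
    expect_identical(adjacencyMatrix(pa[[k]]), adjacencyMatrix(pb[[k]]))
  }
})

test_that("thresholding is invariant under strictly monotone transforms", {
  net <- randomWeightedNetwork(10, seed = 3)
  w <- weightMatrix(net)
  costs <- costLevels(costGrid(10))[c(5, 20, 45)]
  for (f in list(function(x) x^2, sqrt, exp)) {
    tw <- f(w)
    diag(tw) <- 0
    tnet <- weightedNetwork(tw)
    for (cost in costs) {
      expect_identical(adjacencyMatrix(thresholdAtCost(tnet, cost)),
                       adjacencyMatrix(thresholdAtCost(net, cost)))
    }
  }
})
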