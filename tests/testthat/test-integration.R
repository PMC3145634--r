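test_that("integrateExact is a pmf-weighted sum over thresholded graphs", {
  net <- randomWeightedNetwork(9, seed = 13)
  grid <- costGrid(9)
  u <- uniformCostDistribution(grid)
  # constant metric integrates to the constant under any distribution
  expect_equal(integrateExact(net, function(g) 0.7, u), 0.7)
  bb <- betaBinomialCostDistribution(grid, 2, 4)
  expect_equal(integrateExact(net, function(g) 0.7, bb), 0.7)
  # point mass reproduces the metric at that cost
  for (cost in costLevels(grid)[c(3, 17, 30)]) {
    pm <- pointMassCostDistribution(grid, cost)
    expect_equal(integrateExact(net, "globalEfficiency", pm),
                 globalEfficiency(thresholdAtCost(net, cost)))
  }
  # custom callable agrees with the built-in fast path
  expect_equal(integrateExact(net, function(g) globalEfficiency(g), u),
               integrateExact(net, "globalEfficiency", u), tolerance = 1e-14)
  expect_equal(integrateExact(net, function(g) localEfficiency(g), bb),
               integrateExact(net, "localEfficiency", bb), tolerance = 1e-14)
  # size mismatch is an error
  expect_error(integrateExact(net, "globalEfficiency",
                              uniformCostDistribution(costGrid(5))),
               "differ")
})

test_that("the efficiency curve averages back to the integral", {
  net <- randomWeightedNetwork(10, seed = 4)
  grid <- costGrid(10)
  cv <- efficiencyCurve(net, "globalEfficiency")
  u <- uniformCostDistribution(grid)
  expect_equal(sum(pmf(u) * cv$value), integrateExact(net, "globalEfficiency", u))
  bb <- betaBinomialCostDistribution(grid, 3, 3)
  expect_equal(sum(pmf(bb) * cv$value), integrateExact(net, "globalEfficiency", bb))
  expect_equal(cv$value[nrow(cv)], globalEfficiency(thresholdAtCost(net, 1)))
})

test_that("two-node networks attain maximal integrated efficiency", {
  pair <- twoNodePair(0.2, 0.9)
  u <- uniformCostDistribution(costGrid(2))
  expect_equal(integrateExact(pair$first, "globalEfficiency", u), 1)
  expect_equal(integrateExact(pair$second, "globalEfficiency", u), 1)
  # retaining the null cost halves the value — why the grid excludes it
  u0 <- uniformCostDistribution(costGrid(2, includeNull = TRUE))
  expect_equal(integrateExact(pair$first, "globalEfficiency", u0), 0.5)
})

test_that("cost-integrated metrics are invariant under monotone transforms", {
  transforms <- list(function(x) x^2, sqrt, function(x) 0.5 + 0.5 * x, exp)
  net <- randomWeightedNetwork(12, seed = 31)
  grid <- costGrid(12)
  dists <- list(uniformCostDistribution(grid),
                betaBinomialCostDistribution(grid, 3, 3),
                restrictToInterval(uniformCostDistribution(grid), 10 / 66, 40 / 66))
  for (metric in c("globalEfficiency", "localEfficiency")) {
    for (d in dists) {
      ref <- integrateExact(net, metric, d)
      for (f in transforms) {
        tw <- f(weightMatrix(net))
        diag(tw) <- 0
        expect_equal(integrateExact(weightedNetwork(tw), metric, d), ref,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("proportional pairs separate weighted cost from topology", {
  pair <- proportionalPair(randomWeightedNetwork(14, seed = 17), 0.5)
  expect_equal(weightedCost(pair$scaled), 0.5 * weightedCost(pair$base))
  grid <- costGrid(14)
  for (d in list(uniformCostDistribution(grid),
                 betaBinomialCostDistribution(grid, 2, 2))) {
    expect_equal(integrateExact(pair$scaled, "globalEfficiency", d),
                 integrateExact(pair$base, "globalEfficiency", d))
  }
  # fixed absolute cutoff: the denser network dominates
  cutoff <- 0.5
  gBase <- binaryGraph((weightMatrix(pair$base) > cutoff) * 1L)
  gScaled <- binaryGraph((weightMatrix(pair$scaled) > cutoff) * 1L)
  expect_gte(globalEfficiency(gBase), globalEfficiency(gScaled))
  expect_true(all(adjacencyMatrix(gBase)[adjacencyMatrix(gScaled) == 1L] == 1L))
})

test_that("interval integration equals integration against the restricted pmf", {
  net <- randomWeightedNetwork(10, seed = 23)
  grid <- costGrid(10)
  lo <- 10 / 45
  hi <- 30 / 45
  byInterval <- integrateOverInterval(net, "globalEfficiency", lo, hi)
  byDist <- integrateExact(net, "globalEfficiency",
                           restrictToInterval(uniformCostDistribution(grid),
                                              lo, hi))
  expect_equal(byInterval, byDist)
  # full-grid bounds reduce to the plain uniform integral
  expect_equal(integrateOverInterval(net, "globalEfficiency", 1 / 45, 1),
               integrateExact(net, "globalEfficiency",
                              uniformCostDistribution(grid)))
})
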