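test_that("storage success is deterministic and behaves at the extremes", {
  a <- storageSuccess(101, 0.2, eps = 1, gamma = 6, b = 0, seed = 71)
  b <- storageSuccess(101, 0.2, eps = 1, gamma = 6, b = 0, seed = 71)
  expect_identical(as.logical(a), as.logical(b))
  expect_true(as.logical(a))

  ## far below capacity at eps = 0 (fine learning rate)
  ok <- storageSuccess(101, 0.1, eps = 0, gamma = 6, b = 0, seed = 72,
                       maxSweeps = 4000)
  expect_true(as.logical(ok))

  ## far above the Gardner bound
  bad <- storageSuccess(101, 3, eps = 0.3, gamma = 6, b = 0, seed = 73,
                        maxSweeps = 100)
  expect_false(as.logical(bad))
  expect_false(attr(bad, "converged"))
  expect_error(storageSuccess(101, 0, eps = 1), "alpha")
})

test_that("capacity curves interpolate the half-success crossing", {
  ## a degenerate one-point curve is 0 or 1
  cc <- capacityCurve(81, eps = 1, gamma = 6, b = 0, alphaGrid = 0.15,
                      nSeeds = 1, seed = 74, maxSweeps = 300)
  expect_true(cc@successProb %in% c(0, 1))

  ## interpolation logic on a directly constructed curve
  syn <- new("CapacityCurve", alphaGrid = c(0.5, 1.0, 1.5, 2.0),
             successProb = c(1, 0.9, 0.3, 0), nSeeds = 10L,
             details = data.frame())
  expect_equal(alphaAt(syn, 0.5), 1.0 + 0.5 * (0.9 - 0.5) / (0.9 - 0.3))
  expect_equal(alphaAt(syn, 0.95), 0.75)
  allPass <- new("CapacityCurve", alphaGrid = c(0.1, 0.2),
                 successProb = c(1, 1), nSeeds = 1L, details = data.frame())
  expect_equal(alphaAt(allPass, 0.5), 0.2)
})

test_that("eps optimization scans its grid and rejects empty ones", {
  expect_error(optimizeOverEps(101, epsGrid = numeric(0),
                               alphaGrid = c(0.1)), "epsGrid")
  opt <- optimizeOverEps(81, gamma = 6, b = 0, epsGrid = c(0.5, 2),
                         alphaGrid = c(0.1, 0.3), nSeeds = 1, seed = 75,
                         maxSweeps = 200)
  expect_true(opt$bestEps %in% c(0.5, 2))
  expect_equal(nrow(opt$table), 2L)
  expect_true(all(opt$table$alphaHalf >= 0))
})

test_that("no external drive means no storage", {
  ## gamma = 0: the field never separates the populations
  ml <- maxLoad(101, eps = 0.3, gamma = 0, b = 0, alphaGrid = c(0.05, 0.1),
                seed = 76, maxSweeps = 60)
  expect_equal(ml, 0)
})

test_that("the sparse regime stores more than the dense regime at matched eps", {
  ## theory: capacity ordering at equal K
  w <- as.numeric(rectifiedMoments()["mean"])
  expect_gt(alphaC(criticalCapacity(0.2, 3 / w)),
            alphaC(criticalCapacity(0.5, 3 / w)))
  ## scaled simulation: a load between the two capacities succeeds at
  ## f = 0.2 and fails at f = 0.5
  okSparse <- storageSuccess(301, 0.3, eps = 3, gamma = 12, f = 0.2, b = 0,
                             seed = 77, maxSweeps = 400)
  okDense <- storageSuccess(301, 0.3, eps = 3, gamma = 6, f = 0.5, b = 0,
                            seed = 77, maxSweeps = 400)
  expect_true(as.logical(okSparse))
  expect_false(as.logical(okDense))
})

test_that("category-correlated patterns are stored like independent ones", {
  ## capacity is flat in the prototype correlation over the tested range
  for (cc in c(0, 0.6)) {
    ok <- storageSuccess(301, 0.15, eps = 3, gamma = 12, f = 0.2, b = 0,
                         seed = 78, maxSweeps = 400,
                         correlation = if (cc > 0) cc else NULL,
                         nCategories = 5)
    expect_true(as.logical(ok))
  }
})

test_that("rule comparison reports exact agreement at strong drive", {
  cmp <- compareRules(101, eps = 3, gamma = 12, alphaGrid = c(0.2),
                      nSamples = 2, seed = 79, maxSweeps = 300)
  expect_equal(cmp$median, 0)
  expect_equal(cmp$maxDiff, 0)
  expect_equal(cmp$success3TLR, cmp$successPLR)
})
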