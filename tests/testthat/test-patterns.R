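test_that("random patterns hit the requested coding level", {
  ps <- generatePatterns(1001, 100, 0.5, seed = 1)
  se <- sqrt(0.25 / (1001 * 100))
  expect_lt(abs(mean(patterns(ps)) - 0.5), 3 * se)
  expect_true(all(patterns(ps) %in% c(0L, 1L)))

  ps2 <- generatePatterns(500, 100, 0.2, seed = 2)
  se2 <- sqrt(0.2 * 0.8 / (500 * 100))
  expect_lt(abs(mean(patterns(ps2)) - 0.2), 3 * se2)
})

test_that("degenerate coding level near 1 gives the all-ones pattern", {
  ps <- generatePatterns(10, 1, 1 - 1e-12, seed = 3)
  expect_equal(as.vector(patterns(ps)), rep(1L, 10))
})

test_that("distinct patterns are statistically independent", {
  ps <- generatePatterns(1000, 2, 0.5, seed = 4)
  r <- cor(patterns(ps)[1, ], patterns(ps)[2, ])
  expect_lt(abs(r), 3 / sqrt(1000))
})

test_that("pattern generation is reproducible and extendable", {
  a <- generatePatterns(50, 5, 0.5, seed = 7)
  b <- generatePatterns(50, 5, 0.5, seed = 7)
  expect_identical(patterns(a), patterns(b))
  bigger <- generatePatterns(50, 9, 0.5, seed = 7)
  expect_identical(patterns(bigger)[1:5, ], patterns(a))
  other <- generatePatterns(50, 5, 0.5, seed = 8)
  expect_false(identical(patterns(a), patterns(other)))
})

test_that("invalid generator parameters are rejected", {
  expect_error(generatePatterns(100, 10, 0), "codingLevel")
  expect_error(generatePatterns(100, 10, 1.2), "codingLevel")
  expect_error(generatePatterns(1, 10, 0.5), "nUnits")
  expect_error(generateCategorizedPatterns(100, 5, 2, 0.5, -0.1), "correlation")
  expect_error(generateCategorizedPatterns(100, 5, 2, 0.5, 1.5), "correlation")
})

test_that("categorized patterns realize the prototype correlation", {
  ## c = 1: every pattern equals its prototype
  full <- generateCategorizedPatterns(200, 3, 4, 0.3, 1, seed = 10)
  for (mu in seq_len(nPatterns(full)))
    expect_identical(patterns(full)[mu, ],
                     full@prototypes[full@categoryOf[mu], ])

  ## c = 0: independent of the prototype
  none <- generateCategorizedPatterns(1000, 2, 30, 0.5, 0, seed = 11)
  rs <- vapply(seq_len(nPatterns(none)), function(mu)
    cor(patterns(none)[mu, ], none@prototypes[none@categoryOf[mu], ]),
    numeric(1))
  expect_lt(abs(mean(rs)), 3 / sqrt(1000 * 60))

  ## c = 0.75 at f = 0.2: mean empirical correlation within 0.03
  mid <- generateCategorizedPatterns(1000, 5, 24, 0.2, 0.75, seed = 12)
  rs <- vapply(seq_len(nPatterns(mid)), function(mu)
    cor(patterns(mid)[mu, ], mid@prototypes[mid@categoryOf[mu], ]),
    numeric(1))
  expect_lt(abs(mean(rs) - 0.75), 0.03)
})

test_that("pattern-pair correlations are c^2 within / 0 between categories", {
  ps <- generateCategorizedPatterns(1000, 4, 12, 0.5, 0.6, seed = 13)
  X <- patterns(ps); g <- ps@categoryOf
  within <- c(); between <- c()
  for (a in 1:(nrow(X) - 1)) for (b in (a + 1):nrow(X)) {
    r <- cor(X[a, ], X[b, ])
    if (g[a] == g[b]) within <- c(within, r) else between <- c(between, r)
  }
  ## each pair correlation has sd ~ 1/sqrt(N); averages tighten accordingly
  expect_lt(abs(mean(within) - 0.36), 3 / sqrt(1000 * length(within)) + 0.01)
  expect_lt(abs(mean(between)), 3 / sqrt(1000 * length(between)) + 0.01)
})

test_that("plain-text serialization round-trips losslessly", {
  f <- withr::local_tempfile(fileext = ".txt")
  ps <- generateCategorizedPatterns(40, 3, 5, 0.3, 0.8, seed = 14)
  writePatterns(ps, f)
  back <- readPatterns(f)
  expect_identical(patterns(back), patterns(ps))
  expect_identical(back@categoryOf, ps@categoryOf)
  expect_identical(back@prototypes, ps@prototypes)
  expect_equal(back@correlation, ps@correlation)
  expect_equal(codingLevel(back), codingLevel(ps))

  plain <- generatePatterns(33, 7, 0.5, seed = 15)
  writePatterns(plain, f)
  expect_identical(patterns(readPatterns(f)), patterns(plain))
})
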