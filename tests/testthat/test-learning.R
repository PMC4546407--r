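test_that("learning thresholds bracket theta symmetrically", {
  par <- networkParams(1001, f = 0.5, psi = 0.35, gamma = 6)
  th <- learningThresholds(par, eps = 0)
  ## gamma part equals the exact clamped-field shift H1 = f*gamma*sqrt(N-1),
  ## i.e. 350 -/+ (gamma+eps)*f*sqrt(N) up to O(1/sqrt(N))
  expect_equal(as.numeric(th["theta0"]), 350 - 3 * sqrt(1000), tolerance = 1e-12)
  expect_equal(as.numeric(th["theta1"]), 350 + 3 * sqrt(1000), tolerance = 1e-12)
  expect_lt(abs(th["theta0"] - (350 - 3 * sqrt(1001))), 0.05)

  th0 <- learningThresholds(par, eps = 0, gamma = 0)
  expect_equal(as.numeric(th0["theta0"]), 350)
  expect_equal(as.numeric(th0["theta1"]), 350)

  for (eps in c(0.3, 1.7)) {
    th <- learningThresholds(par, eps = eps)
    expect_equal(mean(th), 350)
    expect_equal(as.numeric(diff(th)),
                 2 * (6 * 0.5 * sqrt(1000) + eps * 0.5 * sqrt(1001)))
  }
  expect_error(learningThresholds(par, eps = -1), "eps")
})

test_that("eps = 0 switches to the fine-learning-rate protocol", {
  par <- networkParams(101, f = 0.5, gamma = 6)
  cfg0 <- learningConfig(par, eps = 0)
  expect_equal(cfg0@eta, 0.001)
  expect_equal(cfg0@maxSweeps, 10000L)
  cfg <- learningConfig(par, eps = 0.3)
  expect_equal(cfg@eta, 0.01)
  expect_equal(cfg@maxSweeps, 1000L)
  expect_false(cfg@recalibrateH0)
  expect_true(learningConfig(networkParams(101, f = 0.2, gamma = 12),
                             eps = 0.3)@recalibrateH0)
})

test_that("the three-threshold update acts only inside its field windows", {
  N <- 5L
  par <- new("NetworkParams", N = N, f = 0.5, theta = 10, psi = 10 / (N - 1),
             lambda = 1, gamma = 6, X = 6 * sqrt(N), H0 = 0, H1 = 0)
  cfg <- new("LearningConfig", eta = 0.1, eps = 0, gamma = 6,
             theta0 = 5, theta1 = 15, maxSweeps = 1L, recalibrateH0 = FALSE)
  W0 <- matrix(0.5, N, N); diag(W0) <- 0
  W0[2, 4] <- 0.05                      # will clip at zero under depression
  s <- c(1L, 0L, 1L, 1L, 0L)            # presynaptic states
  v <- c(7,                             # depression window (theta0, theta)
         12,                            # potentiation window (theta, theta1)
         4,                             # below theta0: no plasticity
         16,                            # above theta1: no plasticity
         10)                            # exactly theta: no plasticity
  up <- weights(threeThresholdUpdate(new("WeightMatrix", W = W0), s, v, par, cfg))
  expect_equal(up[1, ], pmax(W0[1, ] - 0.1 * s, 0) * c(0, 1, 1, 1, 1))
  expect_equal(up[2, c(1, 3)], W0[2, c(1, 3)] + 0.1)   # active presyn gain eta
  expect_equal(up[2, 5], W0[2, 5])                     # inactive presyn: no change
  expect_equal(up[2, 4], 0.15)
  expect_equal(up[3, ], W0[3, ])                       # no-plasticity rows
  expect_equal(up[4, ], W0[4, ])
  expect_equal(up[5, ], W0[5, ])
  expect_true(all(diag(up) == 0))
  expect_true(all(up >= 0))

  ## boundary fields theta0 / theta1 exactly: open intervals, no change
  vb <- c(5, 15, 5, 15, 15)
  expect_identical(weights(threeThresholdUpdate(new("WeightMatrix", W = W0),
                                                s, vb, par, cfg)), W0)
})

test_that("zero depression clips at the excitatory bound", {
  N <- 4L
  par <- new("NetworkParams", N = N, f = 0.5, theta = 10, psi = 10 / (N - 1),
             lambda = 1, gamma = 6, X = 1, H0 = 0, H1 = 0)
  cfg <- new("LearningConfig", eta = 0.2, eps = 0, gamma = 6,
             theta0 = 5, theta1 = 15, maxSweeps = 1L, recalibrateH0 = FALSE)
  W0 <- matrix(0, N, N)
  up <- weights(threeThresholdUpdate(new("WeightMatrix", W = W0),
                                     rep(1L, N), rep(7, N), par, cfg))
  expect_identical(up, W0)
})

test_that("a strong external field clamps the network to the pattern", {
  net <- denseNetwork(1001, seed = 31)
  xi <- patterns(generatePatterns(1001, 1, 0.5, seed = 32))[1, ]
  cfg <- learningConfig(net$par, eps = 1.2)
  set.seed(33)
  s0 <- as.integer(runif(1001) < 0.5)
  out <- presentAndLearn(net$W, xi, net$par, cfg, state = s0)
  expect_identical(out$state, xi)
})

test_that("learning with zero rate leaves the weights untouched", {
  net <- denseNetwork(101, seed = 34)
  xi <- patterns(generatePatterns(101, 1, 0.5, seed = 35))[1, ]
  cfg <- learningConfig(net$par, eps = 1)
  cfg@eta <- 0
  out <- presentAndLearn(net$W, xi, net$par, cfg)
  expect_identical(weights(out$weights), weights(net$W))
})

test_that("repeated presentation depletes the plasticity windows", {
  net <- denseNetwork(151, seed = 36)
  xi <- patterns(generatePatterns(151, 1, 0.5, seed = 37))[1, ]
  cfg <- learningConfig(net$par, eps = 1)
  W <- net$W
  for (k in 1:400) {
    out <- presentAndLearn(W, xi, net$par, cfg, state = xi)
    if (identical(weights(out$weights), weights(W))) break
    W <- out$weights
  }
  expect_lt(k, 400)              # reaches a no-op presentation
  ## all clamped fields have left the open window (theta0, theta1)
  v <- localFields(W, xi, net$par@X * xi, net$par)
  expect_true(all(v <= cfg@theta0 | v >= cfg@theta1))
  again <- presentAndLearn(W, xi, net$par, cfg, state = xi)
  expect_identical(weights(again$weights), weights(W))
})

test_that("training converges below capacity and certifies a robust gap", {
  run <- trainedDense(N = 301, alpha = 0.15, eps = 1.2, seed = 41)
  fit <- run$fit
  expect_true(fit@converged)
  expect_equal(tail(fit@errorsPerSweep, 1), 0)
  M <- weights(fit)
  expect_true(all(M >= 0))
  expect_true(all(diag(M) == 0))
  ## ON/OFF field gap per pattern at least 2*f*eps*sqrt(N)
  gapNeeded <- 2 * 0.5 * 1.2 * sqrt(301)
  Xi <- patterns(run$ps)
  for (mu in seq_len(nrow(Xi))) {
    v <- localFields(fit, Xi[mu, ], NULL, run$par)
    on <- Xi[mu, ] == 1
    expect_gte(min(v[on]) - max(v[!on]), gapNeeded)
  }
})

test_that("an empty pattern set converges immediately", {
  net <- denseNetwork(51, seed = 42)
  cfg <- learningConfig(net$par, eps = 1)
  fit <- train3TLR(net$W, generatePatterns(51, 0, 0.5), net$par, cfg, seed = 1)
  expect_true(fit@converged)
  expect_identical(weights(fit), weights(net$W))
})

test_that("far above the Gardner bound training cannot converge", {
  net <- denseNetwork(51, seed = 43)
  ps <- generatePatterns(51, 153, 0.5, seed = 44)   # alpha = 3 > 2
  cfg <- learningConfig(net$par, eps = 0.3)
  cfg@maxSweeps <- 120L
  fit <- train3TLR(net$W, ps, net$par, cfg, seed = 45)
  expect_false(fit@converged)
  expect_equal(fit@sweepsUsed, 120L)
  expect_gt(tail(fit@errorsPerSweep, 1), 0)
})

test_that("the perceptron baseline solves a small separable problem", {
  net <- denseNetwork(20, seed = 46)
  ps <- generatePatterns(20, 5, 0.5, seed = 47)
  cfg <- learningConfig(net$par, eps = 0.3)
  fit <- trainPLR(net$W, ps, net$par, cfg, seed = 48)
  expect_true(fit@converged)
  ## oracle: brute-force stability check of every pattern
  Xi <- patterns(ps)
  for (mu in seq_len(nrow(Xi))) {
    v <- bruteFields(fit@weights, Xi[mu, ], numeric(20), net$par)
    expect_identical(as.integer(v - net$par@theta > 0), Xi[mu, ])
  }
})

test_that("3TLR and PLR are exactly equivalent at strong external drive", {
  N <- 101
  W <- initializeWeights(N, seed = 51)
  par <- networkParams(N, f = 0.5, psi = 0.35, gamma = 12,
                       meanW = meanWeight(W), sdW = sdWeight(W))
  ps <- generatePatterns(N, 30, 0.5, seed = 52)
  cfg <- learningConfig(par, eps = 3)
  cfg@maxSweeps <- 400L
  f3 <- train3TLR(W, ps, par, cfg, seed = 53)
  fp <- trainPLR(W, ps, par, cfg, seed = 53)
  expect_identical(weights(f3), weights(fp))
  expect_identical(f3@sweepsUsed, fp@sweepsUsed)
})

test_that("Hopfield weights store single patterns with their complements", {
  ps <- generatePatterns(80, 1, 0.5, seed = 54)
  W <- trainHopfield(ps)
  expect_identical(W, t(W))
  expect_true(all(diag(W) == 0))
  xi <- 2 * patterns(ps)[1, ] - 1
  expect_equal(as.vector(hopfieldDynamics(W, cbind(xi), 5)), xi)
  expect_equal(as.vector(hopfieldDynamics(W, cbind(-xi), 5)), -xi)
})

test_that("Hopfield retrieval is intact below the breakdown load", {
  ps <- generatePatterns(500, 50, 0.5, seed = 55)   # alpha = 0.10 < 0.138
  W <- trainHopfield(ps)
  expect_gt(min(hopfieldOverlaps(W, ps)), 0.95)
})
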