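test_that("rectified-Gaussian initialization has the calibrated moments", {
  W <- initializeWeights(1001, seed = 1)
  M <- weights(W)
  expect_true(all(M >= 0))
  expect_true(all(diag(M) == 0))

  ## independent oracle: numerical integration of max(0, Normal(1,1)) moments
  m1 <- integrate(function(x) x * dnorm(x, 1, 1), 0, Inf)$value
  m2 <- integrate(function(x) x^2 * dnorm(x, 1, 1), 0, Inf)$value
  expect_equal(m1, 1.0833, tolerance = 1e-4)
  expect_lt(abs(meanWeight(W) - m1), 0.01)
  expect_lt(abs(sdWeight(W) / sqrt(m2 - m1^2) - 1), 0.01)
  expect_equal(as.numeric(rectifiedMoments()["mean"]), m1, tolerance = 1e-10)
  expect_equal(as.numeric(rectifiedMoments()["sd"]), sqrt(m2 - m1^2),
               tolerance = 1e-10)

  expect_identical(weights(initializeWeights(100, seed = 5)),
                   weights(initializeWeights(100, seed = 5)))
})

test_that("inhibition calibration matches its closed form", {
  ## dense regime: the quantile term vanishes, H0 = 1000*(0.54 - 0.35)
  inh <- deriveInhibition(1001, 0.5, psi = 0.35, gamma = 6,
                          meanW = 1.08, sdW = 0.87)
  expect_equal(as.numeric(inh["H0"]), 190, tolerance = 1e-12)
  expect_equal(as.numeric(inh["H1"]), 0.5 * 6 * sqrt(1000), tolerance = 1e-12)

  expect_equal(as.numeric(deriveInhibition(1001, 0.5, psi = 0.35, gamma = 0,
                                           meanW = 1.08, sdW = 0.87)["H1"]), 0)
  ## away from f = 0.5 the sigma_w quantile term contributes
  inh2 <- deriveInhibition(1001, 0.2, psi = 0.35, gamma = 12,
                           meanW = 1.08, sdW = 0.87)
  expect_equal(as.numeric(inh2["H0"]),
               1000 * (0.2 * 1.08 - 0.35) +
                 qnorm(0.2, lower.tail = FALSE) * sqrt(1000 * 0.2) * 0.87,
               tolerance = 1e-12)
  expect_error(deriveInhibition(100, 1.5, meanW = 1, sdW = 1), "f")
})

test_that("network parameters satisfy their structural identities", {
  par <- networkParams(1001, f = 0.5, psi = 0.35, gamma = 6)
  expect_equal(par@theta, 350)
  expect_equal(par@X, 2 * par@H1)          # symmetric +/- H1 population shifts
  expect_equal(par@X, 6 * sqrt(1000))      # = gamma*sqrt(N) up to O(1/N)
  expect_true(validObject(par))
})

test_that("local fields reduce to the printed special cases", {
  net <- denseNetwork(101, seed = 2)
  N <- 101; par <- net$par
  ## zero state, zero external: every v_i = -H0 + lambda*f*N
  v <- localFields(net$W, integer(N), NULL, par)
  expect_equal(v, rep(-par@H0 + par@lambda * par@f * N, N))
  ## at reference activity the inhibition equals H0 exactly
  s <- c(rep(1L, round(par@f * N)), rep(0L, N - round(par@f * N)))
  v <- localFields(net$W, s, NULL, par)
  expect_equal(v, as.vector(weights(net$W) %*% s) -
                 (par@H0 + par@lambda * (sum(s) - par@f * N)))
  ## external pattern adds x_i and engages the inhibitory reaction H1
  xi <- generatePatterns(N, 1, 0.5, seed = 3)
  x <- par@X * patterns(xi)[1, ]
  v <- localFields(net$W, s, x, par)
  expect_equal(v, as.vector(weights(net$W) %*% s) + x -
                 (par@H0 + par@H1 + par@lambda * (sum(s) - par@f * N)))
  expect_error(localFields(net$W, s[-1], NULL, par), "length")
})

test_that("a field exactly at threshold leaves the unit inactive", {
  ## strict Heaviside: Theta(0) = 0
  N <- 4L
  W <- new("WeightMatrix", W = matrix(0, N, N))
  par <- new("NetworkParams", N = N, f = 0.5, theta = 3 * 0.35, psi = 0.35,
             lambda = 0, gamma = 0, X = 0, H0 = -3 * 0.35, H1 = 0)
  ## v_i = -H0 = theta exactly for every unit
  expect_equal(localFields(W, integer(N), NULL, par), rep(par@theta, N))
  expect_equal(stepNetwork(W, integer(N), NULL, par), rep(0L, N))
})

test_that("synchronous step agrees with a brute-force oracle", {
  set.seed(42)
  net <- denseNetwork(8, seed = 6)
  ## all 2^8 states, exact agreement
  for (k in 0:255) {
    s <- as.integer(intToBits(k)[1:8])
    v <- bruteFields(net$W, s, numeric(8), net$par)
    expect_identical(stepNetwork(net$W, s, NULL, net$par),
                     as.integer(v - net$par@theta > 0))
  }
  ## and with an external field applied
  x <- net$par@X * c(1, 0, 1, 0, 1, 0, 1, 0)
  for (k in sample(0:255, 20)) {
    s <- as.integer(intToBits(k)[1:8])
    v <- bruteFields(net$W, s, x, net$par)
    expect_identical(stepNetwork(net$W, s, x, net$par),
                     as.integer(v - net$par@theta > 0))
  }
})

test_that("free dynamics detects fixed points and 2-cycles", {
  N <- 6L
  ## zero weights, strong oscillatory inhibition: all-off <-> all-on 2-cycle
  W <- new("WeightMatrix", W = matrix(0, N, N))
  par <- new("NetworkParams", N = N, f = 0.5, theta = 5 * 0.35, psi = 0.35,
             lambda = 10, gamma = 0, X = 0, H0 = -20, H1 = 0)
  res <- runDynamics(W, integer(N), par, maxSteps = 30)
  expect_false(res$converged)
  expect_lt(res$nSteps, 30)    # cycle detected early

  ## a state that is already a fixed point converges in one step
  net <- trainedDense(101, alpha = 0.1, eps = 1)
  expect_true(net$fit@converged)
  xi <- patterns(net$ps)[1, ]
  res <- runDynamics(net$fit, xi, net$par, maxSteps = 30)
  expect_true(res$converged)
  expect_equal(res$nSteps, 1L)
  expect_identical(res$finalState, xi)
})

test_that("the untrained network self-stabilizes at activity f", {
  ## dense regime, from sparse and from near-saturated initial states
  net <- denseNetwork(1001, seed = 7)
  for (a0 in c(0.1, 0.5, 0.9)) {
    set.seed(100 + round(10 * a0))
    s <- as.integer(runif(1001) < a0)
    for (t in 1:5) s <- stepNetwork(net$W, s, NULL, net$par)
    expect_lt(abs(mean(s) - 0.5), 0.05)
  }
  ## sparse regime (f = 0.2): stable from states at or above f; very low
  ## activity flows to the quiescent state, which is tolerated by design
  W <- initializeWeights(1001, seed = 8)
  par <- networkParams(1001, f = 0.2, psi = 0.35, gamma = 12,
                       meanW = meanWeight(W), sdW = sdWeight(W))
  for (a0 in c(0.2, 0.6)) {
    set.seed(200 + round(10 * a0))
    s <- as.integer(runif(1001) < a0)
    for (t in 1:5) s <- stepNetwork(W, s, NULL, par)
    expect_lt(abs(mean(s) - 0.2), 0.05)
  }
})

test_that("parameter recalibration only moves the quantile term of H0", {
  net <- trainedDense(151, alpha = 0.2, eps = 1, seed = 21)
  par2 <- recalibratedParams(net$par, net$fit)
  expect_equal(par2@lambda, net$par@lambda)
  ## dense regime: quantile term vanishes, so H0 is unchanged
  expect_equal(par2@H0, net$par@H0)
})
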