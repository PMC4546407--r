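## Shared fixtures, built in code at test time.

## A freshly initialized dense-regime network at Table-style parameters.
denseNetwork <- function(N, gamma = 6, seed = 1) {
  W <- initializeWeights(N, seed = seed)
  par <- networkParams(N, f = 0.5, psi = 0.35, gamma = gamma,
                       meanW = meanWeight(W), sdW = sdWeight(W))
  list(W = W, par = par)
}

## Train a small dense network; returns everything a test needs.
trainedDense <- function(N = 201, alpha = 0.15, eps = 1, gamma = 6,
                         seed = 11, maxSweeps = NULL) {
  net <- denseNetwork(N, gamma = gamma, seed = seed)
  ps <- generatePatterns(N, max(1L, round(alpha * N)), 0.5, seed = seed + 1L)
  cfg <- learningConfig(net$par, eps = eps)
  if (!is.null(maxSweeps)) cfg@maxSweeps <- as.integer(maxSweeps)
  fit <- train3TLR(net$W, ps, net$par, cfg, seed = seed + 2L)
  list(W = net$W, par = net$par, ps = ps, cfg = cfg, fit = fit)
}

## Brute-force local fields by explicit double loop (independent oracle for
## the vectorized / compiled implementations).
bruteFields <- function(W, s, x, par) {
  W <- weights(W); N <- nrow(W)
  v <- numeric(N)
  sumS <- sum(s); sumX <- sum(x)
  for (i in seq_len(N)) {
    acc <- 0
    for (j in seq_len(N)) acc <- acc + W[i, j] * s[j]
    ext <- if (sumX > 0) par@H1 else 0
    v[i] <- acc + x[i] - (par@H0 + ext + par@lambda * (sumS - par@f * N))
  }
  v
}
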