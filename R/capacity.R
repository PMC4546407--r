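#' Single storage-success experiment
#'
#' Generates p = round(alpha*N) random patterns at coding level f, initializes
#' weights and inhibition, trains with the three-threshold rule, and checks
#' the storage criterion: every pattern retrieved with rate >= 90% from
#' perturbation fraction b (50 trials, 30 steps, 1% distance tolerance).
#' All randomness derives from `seed`, so the outcome is reproducible.
#'
#' @param N network size.
#' @param alpha load p/N (> 0).
#' @param eps robustness parameter.
#' @param gamma external-field scale.
#' @param f coding level.
#' @param b basin fraction at which success is evaluated.
#' @param seed integer seed.
#' @param psi per-synapse threshold scale.
#' @param nTrials,maxSteps,tol retrieval-criterion settings.
#' @param maxSweeps optional sweep-budget override.
#' @param correlation,nCategories optional category structure for the
#'   patterns (correlation c with L prototypes); NULL generates independent
#'   patterns.
#' @param rule `"3tlr"` (default) or `"plr"`.
#' @return Logical success flag, with attributes `converged` (training
#'   convergence) and `sweeps`.
#' @export
storageSuccess <- function(N, alpha, eps, gamma = 6, f = 0.5, b = 0,
                           seed = NULL, psi = 0.35, nTrials = 50L,
                           maxSteps = 30L, tol = 0.01, maxSweeps = NULL,
                           correlation = NULL, nCategories = 5L,
                           rule = c("3tlr", "plr")) {
  stopIfNot(alpha > 0, "alpha must be > 0")
  rule <- match.arg(rule)
  p <- max(1L, round(alpha * N))
  ps <- if (is.null(correlation))
    generatePatterns(N, p, f, seed = if (is.null(seed)) NULL else deriveSeed(seed, 1L))
  else
    generateCategorizedPatterns(N, nCategories, ceiling(p / nCategories), f,
                                correlation,
                                seed = if (is.null(seed)) NULL else deriveSeed(seed, 1L))
  W0 <- initializeWeights(N, seed = if (is.null(seed)) NULL else deriveSeed(seed, 2L))
  par <- networkParams(N, f = f, psi = psi, gamma = gamma,
                       meanW = meanWeight(W0), sdW = sdWeight(W0))
  cfg <- learningConfig(par, eps = eps)
  if (!is.null(maxSweeps)) cfg@maxSweeps <- as.integer(maxSweeps)
  trainer <- if (rule == "3tlr") train3TLR else trainPLR
  fit <- trainer(W0, ps, par, cfg,
                 seed = if (is.null(seed)) NULL else deriveSeed(seed, 3L))
  ## evaluate retrieval with parameters matched to the trained weights
  parPost <- if (cfg@recalibrateH0) recalibratedParams(par, fit) else par
  res <- basinSize(fit@weights, ps, parPost, bGrid = b, nTrials = nTrials,
                   maxSteps = maxSteps, tol = tol,
                   seed = if (is.null(seed)) NULL else deriveSeed(seed, 4L))
  structure(res@success, converged = fit@converged, sweeps = fit@sweepsUsed)
}

#' Hopfield-baseline storage success under the identical criterion
#'
#' @inheritParams storageSuccess
#' @return Logical success flag.
#' @export
storageSuccessHopfield <- function(N, alpha, b = 0, seed = NULL,
                                   nTrials = 50L, maxSteps = 30L, tol = 0.01) {
  stopIfNot(alpha > 0, "alpha must be > 0")
  p <- max(1L, round(alpha * N))
  ps <- generatePatterns(N, p, 0.5,
                         seed = if (is.null(seed)) NULL else deriveSeed(seed, 1L))
  W <- trainHopfield(ps)
  Xi <- patterns(ps)
  for (mu in seq_len(p)) {
    r <- hopfieldRetrievalRate(W, Xi[mu, ], b, nTrials, maxSteps, tol,
                               seed = if (is.null(seed)) NULL
                                      else deriveSeed(seed, 1000L + mu))
    if (r < 0.9) return(FALSE)
  }
  TRUE
}

#' Success probability as a function of the load
#'
#' Monte-Carlo estimate of the probability of successful storage on a grid of
#' loads, from `nSeeds` independent replicates per load.
#'
#' @inheritParams storageSuccess
#' @param alphaGrid loads to evaluate.
#' @param nSeeds replicates per load (default 10).
#' @param seed master seed.
#' @param ... further arguments passed to [storageSuccess()].
#' @return A [CapacityCurve-class].
#' @export
capacityCurve <- function(N, eps, gamma = 6, f = 0.5, b = 0, alphaGrid,
                          nSeeds = 10L, seed = NULL, ...) {
  rows <- list()
  prob <- numeric(length(alphaGrid))
  for (a in seq_along(alphaGrid)) {
    ok <- logical(nSeeds)
    for (k in seq_len(nSeeds)) {
      sk <- if (is.null(seed)) NULL else deriveSeed(seed, a * 1000L + k)
      ok[k] <- storageSuccess(N, alphaGrid[a], eps, gamma, f, b, seed = sk, ...)
      rows[[length(rows) + 1L]] <- data.frame(alpha = alphaGrid[a], seed = k,
                                              success = ok[k])
    }
    prob[a] <- mean(ok)
  }
  new("CapacityCurve", alphaGrid = alphaGrid, successProb = prob,
      nSeeds = as.integer(nSeeds), details = do.call(rbind, rows))
}

#' @rdname accessors
#' @export
setMethod("alphaAt", "CapacityCurve", function(object, q = 0.5) {
  a <- object@alphaGrid; p <- object@successProb
  if (all(p >= q)) return(max(a))
  if (all(p < q)) return(min(a))
  i <- which(p < q)[1L]            # first load where the probability drops below q
  if (i == 1L) return(min(a))
  p0 <- p[i - 1L]; p1 <- p[i]
  if (p0 == p1) return((a[i - 1L] + a[i]) / 2)
  a[i - 1L] + (p0 - q) / (p0 - p1) * (a[i] - a[i - 1L])
})

setMethod("show", "CapacityCurve", function(object) {
  cat(sprintf("CapacityCurve: %d loads x %d seeds; alpha at p=0.5: %.3f\n",
              length(object@alphaGrid), object@nSeeds, alphaAt(object, 0.5)))
  print(data.frame(alpha = object@alphaGrid, successProb = object@successProb),
        row.names = FALSE)
  invisible(NULL)
})

#' Largest load passing the storage criterion
#'
#' Scans `alphaGrid` upward and returns the largest load at which
#' [storageSuccess()] (or the Hopfield baseline) holds, stopping at the first
#' failure.
#'
#' @inheritParams capacityCurve
#' @param hopfield evaluate the Hebbian baseline instead of the 3TLR network.
#' @return The largest passing load (0 when the first grid point already
#'   fails).
#' @export
maxLoad <- function(N, eps = 0.3, gamma = 6, f = 0.5, b = 0, alphaGrid,
                    seed = NULL, hopfield = FALSE, ...) {
  best <- 0
  for (a in seq_along(alphaGrid)) {
    sk <- if (is.null(seed)) NULL else deriveSeed(seed, a)
    ok <- if (hopfield)
      storageSuccessHopfield(N, alphaGrid[a], b = b, seed = sk, ...)
    else storageSuccess(N, alphaGrid[a], eps, gamma, f, b, seed = sk, ...)
    if (!ok) break
    best <- alphaGrid[a]
  }
  best
}

#' Optimize the robustness parameter at fixed basin size
#'
#' For each eps in `epsGrid`, estimates the 0.5-crossing load of the success
#' probability at basin fraction b, and returns the eps maximizing it (larger
#' basins favour larger margins; at b = 0 the optimum sits at small eps).
#'
#' @inheritParams capacityCurve
#' @param epsGrid robustness values to scan (must be non-empty).
#' @return A list with `bestEps`, `bestAlpha`, and `table` (one row per eps).
#' @export
optimizeOverEps <- function(N, gamma = 6, f = 0.5, b = 0, epsGrid, alphaGrid,
                            nSeeds = 5L, seed = NULL, ...) {
  stopIfNot(length(epsGrid) > 0, "epsGrid must not be empty")
  cap <- numeric(length(epsGrid))
  for (e in seq_along(epsGrid)) {
    cc <- capacityCurve(N, epsGrid[e], gamma, f, b, alphaGrid, nSeeds,
                        seed = if (is.null(seed)) NULL else deriveSeed(seed, e),
                        ...)
    cap[e] <- alphaAt(cc, 0.5)
  }
  i <- which.max(cap)
  list(bestEps = epsGrid[i], bestAlpha = cap[i],
       table = data.frame(eps = epsGrid, alphaHalf = cap))
}

#' Capacity as a function of the external-field strength
#'
#' For each gamma in `gammaGrid`, the maximal load passing the storage
#' criterion within the fixed sweep budget. The capacity plateaus at large
#' gamma (where the rule matches the perceptron rule exactly) and collapses
#' sharply below a critical field strength where the two field bumps of the
#' clamped distribution start to overlap and the rule misreads the desired
#' output.
#'
#' @inheritParams maxLoad
#' @param gammaGrid external-field scales to scan.
#' @return data.frame with columns `gamma` and `maxAlpha`.
#' @export
gammaSweep <- function(N, f = 0.5, eps = 0.3, gammaGrid, alphaGrid,
                       seed = NULL, ...) {
  maxA <- vapply(seq_along(gammaGrid), function(g)
    maxLoad(N, eps = eps, gamma = gammaGrid[g], f = f, b = 0,
            alphaGrid = alphaGrid,
            seed = if (is.null(seed)) NULL else deriveSeed(seed, g), ...),
    numeric(1L))
  data.frame(gamma = gammaGrid, maxAlpha = maxA)
}

#' Direct comparison of the three-threshold and perceptron rules
#'
#' For each load, trains both rules on identical problems with identical
#' pseudo-random streams (same initial weights, same initial state, same
#' presentation permutations) and summarizes the distribution of
#' absolute weight discrepancies |Delta w| over off-diagonal entries, pooled
#' across samples, together with the per-rule convergence probabilities. At
#' strong drive (gamma = 12, f = 0.5) the discrepancies are exactly zero; at
#' gamma = 6 outliers appear close to the three-threshold rule's capacity.
#'
#' @inheritParams capacityCurve
#' @param nSamples independent problems per load (default 10).
#' @return data.frame with one row per load: success probabilities of both
#'   rules and the median / 5th / 95th percentile of |Delta w|.
#' @export
compareRules <- function(N, f = 0.5, eps = 3, gamma = 6, alphaGrid,
                         nSamples = 10L, seed = NULL, psi = 0.35,
                         maxSweeps = NULL) {
  out <- vector("list", length(alphaGrid))
  for (a in seq_along(alphaGrid)) {
    diffs <- c(); ok3 <- okP <- logical(nSamples)
    for (k in seq_len(nSamples)) {
      sk <- if (is.null(seed)) NULL else deriveSeed(seed, a * 1000L + k)
      p <- max(1L, round(alphaGrid[a] * N))
      ps <- generatePatterns(N, p, f,
                             seed = if (is.null(sk)) NULL else deriveSeed(sk, 1L))
      W0 <- initializeWeights(N, seed = if (is.null(sk)) NULL else deriveSeed(sk, 2L))
      par <- networkParams(N, f = f, psi = psi, gamma = gamma,
                           meanW = meanWeight(W0), sdW = sdWeight(W0))
      cfg <- learningConfig(par, eps = eps)
      if (!is.null(maxSweeps)) cfg@maxSweeps <- as.integer(maxSweeps)
      sTrain <- if (is.null(sk)) 1L else deriveSeed(sk, 3L)
      fit3 <- train3TLR(W0, ps, par, cfg, seed = sTrain)
      fitP <- trainPLR(W0, ps, par, cfg, seed = sTrain)
      ok3[k] <- fit3@converged; okP[k] <- fitP@converged
      d <- abs(weights(fit3) - weights(fitP))
      diffs <- c(diffs, d[offDiag(d)])
    }
    qs <- quantile(diffs, c(0.05, 0.5, 0.95), names = FALSE)
    out[[a]] <- data.frame(alpha = alphaGrid[a],
                           success3TLR = mean(ok3), successPLR = mean(okP),
                           q05 = qs[1L], median = qs[2L], q95 = qs[3L],
                           maxDiff = max(diffs))
  }
  do.call(rbind, out)
}

#' Full-scale experiment plans
#'
#' The package's headline experiments at full scale (N = 1001, the published
#' protocol sizes) take hours on a single CPU; the test suite therefore
#' exercises scaled-down versions. This function returns the full-scale
#' configurations as data so they can be dispatched verbatim (e.g. overnight)
#' through [runExperiment()].
#'
#' @return Named list of experiment configurations, each a list of
#'   [runExperiment()] fields.
#' @export
fullScaleTargets <- function() {
  list(
    denseZeroBasin = list(experiment = "capacity", N = 1001, f = 0.5,
                          gamma = 6, eps = 0, b = 0,
                          alphaGrid = seq(1.3, 1.9, by = 0.05), nSeeds = 10,
                          note = "alpha_c approx 1.6 at zero basin size"),
    gammaTransition = list(experiment = "gamma-sweep", N = 1001, f = 0.5,
                           eps = 0.3,
                           gammaGrid = seq(1.6, 6, by = 0.4),
                           alphaGrid = seq(0.2, 1.6, by = 0.1),
                           note = "sharp capacity collapse near gamma = 2.4"),
    sparseRegime = list(experiment = "capacity", N = 1001, f = 0.2,
                        gamma = 12, eps = 1, b = 0,
                        alphaGrid = seq(1.0, 3.0, by = 0.1), nSeeds = 10,
                        note = ">= 70% of the theoretical capacity at f = 0.2"),
    hopfieldRatio = list(experiment = "eps-opt", N = 1001, f = 0.5,
                         gamma = 6, b = 0, epsGrid = c(0, 0.1, 0.3),
                         alphaGrid = seq(1.0, 1.9, by = 0.1), nSeeds = 10,
                         note = ">= 11x the Hopfield capacity at zero basin size"))
}
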