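#' Perturb a stored pattern
#'
#' A uniformly chosen fraction b of the units have their bits resampled
#' Bernoulli(f) independently (a resampled bit may coincide with the original
#' one). The expected normalized Hamming distance from the pattern is
#' 2 f (1-f) b, i.e. b/2 at f = 0.5, so reaching basin size b means
#' recovering from distance b/2 in the dense regime.
#'
#' @param pattern 0/1 vector.
#' @param b fraction of units to randomize, in [0, 1].
#' @param f coding level used for resampling.
#' @param seed optional integer seed.
#' @return Integer 0/1 state vector.
#' @export
perturbPattern <- function(pattern, b, f, seed = NULL) {
  stopIfNot(b >= 0 && b <= 1, "b must lie in [0, 1]")
  N <- length(pattern)
  k <- round(b * N)
  withSeed(seed, {
    s <- as.integer(pattern)
    if (k > 0L) {
      idx <- sample.int(N, k)
      s[idx] <- as.integer(runif(k) < f)
    }
    s
  })
}

## Batched synchronous free dynamics: one trajectory per column of S.
batchedDynamics <- function(Wm, S, params, maxSteps = 30L) {
  N <- nrow(Wm)
  fN <- params@f * N
  for (t in seq_len(maxSteps)) {
    inhib <- params@H0 + params@lambda * (colSums(S) - fN)
    V <- Wm %*% S
    Snew <- (sweep(V, 2L, inhib) - params@theta > 0) + 0L
    if (all(Snew == S)) break
    S <- Snew
  }
  S
}

#' Retrieval rate of one pattern at perturbation level b
#'
#' Fraction of noisy trials in which the free dynamics, started from a
#' perturbation of the pattern at fraction b, ends (whether or not at a fixed
#' point) within normalized Hamming distance `tol` of the pattern in at most
#' `maxSteps` synchronous updates.
#'
#' @param W trained weights ([WeightMatrix-class], [TrainingResult-class] or
#'   matrix).
#' @param pattern the stored 0/1 pattern.
#' @param b perturbation fraction.
#' @param params a [NetworkParams-class].
#' @param nTrials noisy initializations (default 50, the test-phase budget).
#' @param maxSteps dynamics budget (default 30).
#' @param tol normalized-distance criterion (default 0.01).
#' @param seed optional integer seed.
#' @return Retrieval rate in [0, 1].
#' @export
retrievalRate <- function(W, pattern, b, params, nTrials = 50L,
                          maxSteps = 30L, tol = 0.01, seed = NULL) {
  stopIfNot(tol > 0 && tol < 1, "tol must lie in (0, 1)")
  Wm <- asWeightMat(W)
  S0 <- withSeed(seed, vapply(seq_len(nTrials), function(i)
    perturbPattern(pattern, b, params@f), integer(length(pattern))))
  Sfin <- batchedDynamics(Wm, S0, params, maxSteps)
  dist <- colMeans(abs(Sfin - as.integer(pattern)))
  mean(dist <= tol)
}

#' Measure the basin of attraction of a stored pattern set
#'
#' Scans the perturbation grid `bGrid` in increasing order; a pattern set is
#' successfully stored at size b when every pattern's retrieval rate at b is
#' at least 90%. Returns the largest grid value at which the criterion holds
#' (0 when it fails everywhere). The scan stops at the first failing b (the
#' retrieval rate is statistically non-increasing in b).
#'
#' @inheritParams retrievalRate
#' @param patternSet the stored [PatternSet-class].
#' @param bGrid increasing perturbation fractions (default 0 to 1 by 0.05).
#' @return A [RetrievalResult-class].
#' @export
basinSize <- function(W, patternSet, params, bGrid = seq(0, 1, by = 0.05),
                      nTrials = 50L, maxSteps = 30L, tol = 0.01, seed = NULL) {
  stopIfNot(length(bGrid) > 0, "bGrid must not be empty")
  stopIfNot(all(diff(bGrid) > 0) || length(bGrid) == 1L,
            "bGrid must be sorted ascending")
  Wm <- asWeightMat(W)
  Xi <- patterns(patternSet)
  best <- 0; bestRates <- rep(NA_real_, nrow(Xi)); anySuccess <- FALSE
  rows <- list()
  for (k in seq_along(bGrid)) {
    b <- bGrid[k]
    sk <- if (is.null(seed)) NULL else deriveSeed(seed, k)
    rates <- vapply(seq_len(nrow(Xi)), function(mu)
      retrievalRate(Wm, Xi[mu, ], b, params, nTrials, maxSteps, tol,
                    seed = if (is.null(sk)) NULL else deriveSeed(sk, mu)),
      numeric(1L))
    rows[[k]] <- data.frame(b = b, pattern = seq_len(nrow(Xi)), rate = rates)
    if (min(rates) >= 0.9) {
      best <- b; bestRates <- rates; anySuccess <- TRUE
    } else break
  }
  new("RetrievalResult", basinFraction = best,
      rates = if (anySuccess) bestRates else rows[[1L]]$rate,
      nTrials = as.integer(nTrials), success = anySuccess,
      details = do.call(rbind, rows))
}

setMethod("show", "RetrievalResult", function(object) {
  cat(sprintf(paste0("RetrievalResult: basin fraction b = %g (%s), ",
                     "%d trials/pattern,\n  min rate at b = %.3f\n"),
              object@basinFraction,
              if (object@success) "success" else "no b succeeded",
              object@nTrials, min(object@rates)))
  invisible(NULL)
})

## Hopfield analogue of retrievalRate/basin success, under the identical
## perturbation, distance tolerance and step budget, so that capacity
## comparisons between the 3TLR network and the Hebbian baseline use one
## criterion.
hopfieldRetrievalRate <- function(W, pattern, b, nTrials = 50L,
                                  maxSteps = 30L, tol = 0.01, seed = NULL) {
  S0 <- withSeed(seed, vapply(seq_len(nTrials), function(i)
    perturbPattern(pattern, b, 0.5), integer(length(pattern))))
  Sfin <- hopfieldDynamics(W, 2 * S0 - 1, maxSteps)
  dist <- colMeans(abs((Sfin + 1) / 2 - as.integer(pattern)))
  mean(dist <= tol)
}
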