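#' Hopfield baseline: Hebbian weights
#'
#' The classical Hebbian outer-product matrix for +/-1 coded patterns,
#' w_ij = (1/N) sum_mu (2 xi_i - 1)(2 xi_j - 1), zero diagonal, symmetric.
#' Paired with its own +/-1 synchronous dynamics at threshold zero
#' ([hopfieldDynamics()]); the inhibition machinery of the excitatory network
#' is not involved. Weights are signed, so this is a plain matrix, not a
#' [WeightMatrix-class].
#'
#' @param patternSet a [PatternSet-class] (dense coding f = 0.5 is the
#'   regime where the 0.138 N capacity applies).
#' @return Numeric N x N symmetric matrix with zero diagonal.
#' @export
trainHopfield <- function(patternSet) {
  Xi <- 2 * patterns(patternSet) - 1
  N <- ncol(Xi)
  W <- crossprod(Xi) / N
  diag(W) <- 0
  W
}

#' Hopfield +/-1 synchronous dynamics (batched)
#'
#' Runs synchronous sign dynamics s' = sgn(W s) (ties resolved to -1, the
#' analogue of the strict Heaviside convention) on one state per column until
#' every column is at a fixed point or `maxSteps` is reached.
#'
#' @param W Hebbian weight matrix from [trainHopfield()].
#' @param S N x m matrix of +/-1 states, one trajectory per column.
#' @param maxSteps maximum synchronous updates (default 30).
#' @return N x m matrix of final +/-1 states.
#' @export
hopfieldDynamics <- function(W, S, maxSteps = 30L) {
  S <- as.matrix(S)
  for (t in seq_len(maxSteps)) {
    Snew <- ifelse(W %*% S > 0, 1, -1)
    if (all(Snew == S)) return(Snew)
    S <- Snew
  }
  S
}

#' Pattern overlaps after Hopfield retrieval from the stored patterns
#'
#' Initializes the dynamics at every stored pattern and returns the final
#' overlap m_mu = (1/N) sum_i sgn-state_i * pattern_i per pattern. Below the
#' breakdown load the overlaps stay near 1; above it they collapse.
#'
#' @inheritParams hopfieldDynamics
#' @param patternSet the stored [PatternSet-class].
#' @return Numeric vector of per-pattern final overlaps.
#' @export
hopfieldOverlaps <- function(W, patternSet, maxSteps = 30L) {
  Xi <- t(2 * patterns(patternSet) - 1)       # N x p, +/-1
  Sfin <- hopfieldDynamics(W, Xi, maxSteps)
  colMeans(Sfin * Xi)
}

#' Locate the Hopfield retrieval-breakdown load
#'
#' Sweeps the load alpha = p/N over `alphaGrid`: for each load and seed, p
#' random dense patterns are stored with the Hebbian rule, the dynamics is
#' started at every pattern, and the load is marked "retrieving" while the
#' mean final overlap stays at or above `overlapThreshold`. The per-seed
#' breakdown estimate is the midpoint between the last retrieving and the
#' first non-retrieving grid load; the returned estimate is their average.
#'
#' @param N network size (>= 500 for a sharp transition near 0.138).
#' @param alphaGrid increasing loads to scan (default a 0.005-spaced grid
#'   around the transition).
#' @param nSeeds number of independent replicates.
#' @param overlapThreshold mean-overlap criterion for successful retrieval.
#' @param maxSteps dynamics budget per retrieval.
#' @param seed master seed.
#' @return A list with `alphaC` (the breakdown estimate), `perSeed` (per-seed
#'   estimates) and `details` (a data.frame of mean overlaps per load/seed).
#' @export
hopfieldCriticalLoad <- function(N = 500L, alphaGrid = seq(0.115, 0.16, by = 0.005),
                                 nSeeds = 10L, overlapThreshold = 0.95,
                                 maxSteps = 30L, seed = NULL) {
  stopIfNot(all(diff(alphaGrid) > 0), "alphaGrid must be increasing")
  rows <- list()
  perSeed <- numeric(nSeeds)
  for (k in seq_len(nSeeds)) {
    sk <- if (is.null(seed)) NULL else deriveSeed(seed, k)
    m <- numeric(length(alphaGrid))
    for (a in seq_along(alphaGrid)) {
      p <- max(1L, round(alphaGrid[a] * N))
      ps <- generatePatterns(N, p, 0.5,
                             seed = if (is.null(sk)) NULL else deriveSeed(sk, a))
      W <- trainHopfield(ps)
      m[a] <- mean(hopfieldOverlaps(W, ps, maxSteps))
      rows[[length(rows) + 1L]] <- data.frame(seed = k, alpha = alphaGrid[a],
                                              meanOverlap = m[a])
    }
    bad <- which(m < overlapThreshold)
    perSeed[k] <- if (!length(bad)) max(alphaGrid)
      else if (bad[1L] == 1L) min(alphaGrid)
      else (alphaGrid[bad[1L] - 1L] + alphaGrid[bad[1L]]) / 2
  }
  list(alphaC = mean(perSeed), perSeed = perSeed,
       details = do.call(rbind, rows))
}
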