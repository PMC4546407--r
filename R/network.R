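#' Random initial weight matrix
#'
#' Off-diagonal entries are sampled from a Normal(1, 1) distribution and
#' negative draws are set to zero (rectified Gaussian); the diagonal is zero.
#' The resulting off-diagonal mean is E[max(0, Normal(1,1))] =
#' Phi(1) + phi(1) = 1.0833 (the value used for the inhibitory slope lambda)
#' and the off-diagonal standard deviation is 0.8667.
#'
#' @param N network size (>= 2).
#' @param seed optional integer seed.
#' @return A [WeightMatrix-class].
#' @examples
#' W <- initializeWeights(200, seed = 1)
#' meanWeight(W)
#' @export
initializeWeights <- function(N, seed = NULL) {
  stopIfNot(is.numeric(N) && N >= 2, "N must be >= 2")
  N <- as.integer(N)
  W <- withSeed(seed, matrix(pmax(rnorm(N * N, mean = 1, sd = 1), 0), N, N))
  diag(W) <- 0
  new("WeightMatrix", W = W)
}

#' @rdname accessors
#' @export
setMethod("weights", "WeightMatrix", function(object, ...) object@W)
#' @rdname accessors
#' @export
setMethod("meanWeight", "WeightMatrix", function(object)
  mean(object@W[offDiag(object@W)]))
#' @rdname accessors
#' @export
setMethod("sdWeight", "WeightMatrix", function(object)
  sd(object@W[offDiag(object@W)]))

offDiag <- function(W) row(W) != col(W)

setMethod("show", "WeightMatrix", function(object) {
  cat(sprintf("WeightMatrix: %d x %d, wbar = %.4f, sigma_w = %.4f, silent = %.3f\n",
              nrow(object@W), ncol(object@W), meanWeight(object),
              sdWeight(object), silentFraction(object)))
  invisible(NULL)
})

#' Inhibition calibration
#'
#' Computes the basal inhibition H0 and the inhibitory reaction term H1 that
#' make the network self-stabilize at activity level f:
#' \deqn{H_0 = (N-1)(f \bar w - \psi) + H^{-1}(f)\sqrt{(N-1)f}\,\sigma_w,
#'       \qquad H_1 = f \gamma \sqrt{N-1},}
#' where H(x) = erfc(x/sqrt(2))/2 is the Gaussian tail function. The H^{-1}(f)
#' term positions the neuronal threshold at the f-quantile of the recurrent
#' field distribution (field standard deviation sigma_w sqrt((N-1) f)); at
#' f = 0.5 it vanishes exactly, so in the dense regime H0 does not depend on
#' sigma_w.
#'
#' @param N network size.
#' @param f target activity level in (0, 1).
#' @param theta neuronal threshold (defaults to (N-1)*psi).
#' @param psi per-synapse threshold scale.
#' @param gamma external-field scale.
#' @param meanW,sdW mean and standard deviation of the (off-diagonal) weights.
#' @return Named numeric vector with elements `H0` and `H1`.
#' @examples
#' deriveInhibition(1001, 0.5, psi = 0.35, gamma = 6, meanW = 1.08, sdW = 0.87)
#' @export
deriveInhibition <- function(N, f, theta = (N - 1) * psi, psi = 0.35,
                             gamma = 6, meanW, sdW) {
  stopIfNot(f > 0 && f < 1, "f must be in (0, 1)")
  stopIfNot(sdW >= 0, "sdW must be >= 0")
  psi <- theta / (N - 1)
  Hinv <- qnorm(f, lower.tail = FALSE)   # H^{-1}(f); exactly 0 at f = 0.5
  H0 <- (N - 1) * (f * meanW - psi) + Hinv * sqrt((N - 1) * f) * sdW
  H1 <- f * gamma * sqrt(N - 1)
  c(H0 = H0, H1 = H1)
}

#' Construct network parameters
#'
#' Bundles the scalar model parameters and derives theta = (N-1)*psi,
#' the external-field strength X, and the inhibition terms H0, H1 from the
#' weight statistics via [deriveInhibition()]. The field strength is set to
#' X = 2 H1 = 2 f gamma sqrt(N-1) (the dense-regime gamma*sqrt(N) up to
#' O(1/N)): together with the engaged inhibitory reaction H1 a presented
#' pattern then shifts the stimulated and unstimulated populations
#' symmetrically by exactly +/- H1 at any coding level, which is the
#' geometry the learning thresholds assume. The inhibitory slope lambda
#' defaults to the mean weight (its calibrated value) and is held fixed
#' during learning.
#'
#' @param N network size.
#' @param f activity level / coding level.
#' @param psi per-synapse threshold scale (theta = (N-1)*psi).
#' @param gamma external-field scale.
#' @param meanW,sdW weight statistics used for the calibration; defaults are
#'   the rectified-Normal(1,1) initialization values.
#' @param lambda inhibitory feedback slope; defaults to `meanW`.
#' @return A [NetworkParams-class].
#' @examples
#' par <- networkParams(1001, f = 0.5, psi = 0.35, gamma = 6)
#' par@theta   # 350
#' @export
networkParams <- function(N, f = 0.5, psi = 0.35, gamma = 6,
                          meanW = rectifiedMoments()["mean"],
                          sdW = rectifiedMoments()["sd"],
                          lambda = meanW) {
  N <- as.integer(N)
  inh <- deriveInhibition(N, f, psi = psi, gamma = gamma,
                          meanW = as.numeric(meanW), sdW = as.numeric(sdW))
  new("NetworkParams", N = N, f = f, theta = (N - 1) * psi, psi = psi,
      lambda = as.numeric(lambda), gamma = gamma,
      X = 2 * as.numeric(inh["H1"]),
      H0 = as.numeric(inh["H0"]), H1 = as.numeric(inh["H1"]))
}

#' Moments of the rectified Normal(1,1) weight initialization
#'
#' Closed-form mean and standard deviation of max(0, Normal(1,1)):
#' mean = Phi(1) + phi(1), second moment = 2 Phi(1) + phi(1).
#'
#' @return Named numeric vector with `mean` and `sd`.
#' @export
rectifiedMoments <- function() {
  m1 <- pnorm(1) + dnorm(1)
  m2 <- 2 * pnorm(1) + dnorm(1)
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

#' Recalibrate network parameters to a trained weight matrix
#'
#' Recomputes the sigma_w quantile term of H0 from the trained weights,
#' keeping the mean-weight anchor and the inhibitory slope lambda at their
#' initial calibration (taken from `params@lambda`). The quantile term
#' vanishes at f = 0.5; away from the dense regime it moves with the weight
#' spread during learning, so retrieval after training must use the updated
#' value (training itself recalibrates the same way after every sweep when
#' enabled).
#'
#' @param params a [NetworkParams-class].
#' @param W trained weights ([WeightMatrix-class] or [TrainingResult-class]).
#' @return A [NetworkParams-class] with updated H0.
#' @export
recalibratedParams <- function(params, W) {
  if (is(W, "TrainingResult")) W <- W@weights
  if (!is(W, "WeightMatrix")) W <- new("WeightMatrix", W = as.matrix(W))
  networkParams(params@N, f = params@f, psi = params@psi,
                gamma = params@gamma, meanW = params@lambda,
                sdW = sdWeight(W), lambda = params@lambda)
}

setMethod("show", "NetworkParams", function(object) {
  cat(sprintf(paste0("NetworkParams: N = %d, f = %g, theta = %g (psi = %g), ",
                     "lambda = %.4f,\n  gamma = %g (X = %.2f), H0 = %.2f, H1 = %.2f\n"),
              object@N, object@f, object@theta, object@psi, object@lambda,
              object@gamma, object@X, object@H0, object@H1))
  invisible(NULL)
})

#' Local fields of the network
#'
#' Computes v_i = sum_j w_ij s_j + x_i - I(x, s) with the global inhibition
#' I(x, s) = H0 + H1 * 1[x != 0] + lambda * (sum(s) - f N): the inhibitory
#' reaction to an external stimulus is engaged at its calibrated magnitude
#' H1 whenever the stimulus is present (its design value for a pattern at
#' coding level f; tying the reaction to the realized pattern activity
#' instead would couple the learning geometry to per-pattern activity
#' fluctuations). With a zero external field this reduces to the
#' spontaneous-dynamics inhibition I0(s) = H0 + lambda*(sum(s) - f N).
#'
#' @param W a [WeightMatrix-class] or a plain numeric matrix.
#' @param state binary state vector s (length N, entries 0/1).
#' @param external external field vector x (entries 0 or X); defaults to zero.
#' @param params a [NetworkParams-class].
#' @return Numeric vector of local fields v.
#' @export
localFields <- function(W, state, external = NULL, params) {
  W <- asWeightMat(W)
  N <- nrow(W)
  stopIfNot(length(state) == N, "state length must match the network size")
  if (is.null(external)) external <- numeric(N)
  stopIfNot(length(external) == N, "external length must match the network size")
  fN <- params@f * N
  extTerm <- if (any(external != 0)) params@H1 else 0
  inhib <- params@H0 + extTerm + params@lambda * (sum(state) - fN)
  as.vector(W %*% state) + external - inhib
}

asWeightMat <- function(W) {
  if (is(W, "WeightMatrix")) W@W
  else if (is(W, "TrainingResult")) W@weights@W
  else as.matrix(W)
}

#' One synchronous update step
#'
#' All units are updated in parallel from the previous state:
#' s_i' = Theta(v_i - theta) with the strict Heaviside convention
#' Theta(0) = 0, so a field exactly at threshold yields an inactive unit.
#'
#' @inheritParams localFields
#' @return Integer 0/1 state vector.
#' @export
stepNetwork <- function(W, state, external = NULL, params) {
  v <- localFields(W, state, external, params)
  as.integer(v - params@theta > 0)
}

#' Run the free (zero-external-field) dynamics to a fixed point
#'
#' Iterates synchronous updates until the state reproduces its predecessor
#' (fixed point) or `maxSteps` is reached. A period-2 oscillation is detected
#' and reported as non-converged.
#'
#' @inheritParams localFields
#' @param initialState starting 0/1 state.
#' @param maxSteps maximum number of synchronous updates (default 30, the
#'   retrieval-protocol budget).
#' @return A list with `finalState`, `nSteps`, and `converged`.
#' @export
runDynamics <- function(W, initialState, params, maxSteps = 30L) {
  stopIfNot(maxSteps >= 1, "maxSteps must be >= 1")
  W <- asWeightMat(W)
  res <- cppRunDynamics(W, as.integer(initialState), params@H0, params@lambda,
                        params@theta, params@f * nrow(W), as.integer(maxSteps))
  list(finalState = as.integer(res$finalState),
       nSteps = res$nSteps, converged = res$converged)
}
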