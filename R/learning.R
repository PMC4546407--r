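#' Auxiliary learning thresholds
#'
#' The two learning thresholds bracketing the neuronal threshold,
#' theta0/theta1 = theta -/+ (gamma + eps) f sqrt(N) up to O(1/sqrt(N)):
#' the gamma part is the exact field shift produced by the clamped external
#' input (f gamma sqrt(N-1), i.e. +/- H1 through the engaged inhibitory
#' reaction), the eps part adds the robustness margin eps f sqrt(N). With
#' this split, a clamped field outside (theta0, theta1) corresponds exactly
#' to a free field beyond the robust margin around theta, for every pattern.
#'
#' @param params a [NetworkParams-class].
#' @param eps robustness parameter (>= 0).
#' @param gamma external-field scale (defaults to the one in `params`).
#' @return Named numeric vector with `theta0` and `theta1`.
#' @examples
#' par <- networkParams(1001, f = 0.5, gamma = 6)
#' learningThresholds(par, eps = 0)   # ~ 350 -/+ 3*sqrt(1000)
#' @export
learningThresholds <- function(params, eps, gamma = params@gamma) {
  stopIfNot(eps >= 0, "eps must be >= 0")
  half <- gamma * params@f * sqrt(params@N - 1) +
    eps * params@f * sqrt(params@N)
  c(theta0 = params@theta - half, theta1 = params@theta + half)
}

#' Construct a learning configuration
#'
#' Bundles the training-protocol parameters and derives theta0/theta1 via
#' [learningThresholds()]. Defaults follow the simulation protocol:
#' eta = 0.01 with a 1000-sweep budget, switching to eta = 0.001 with 10000
#' sweeps at eps = 0 (where convergence needs the finer step); H0
#' recalibration after each sweep is enabled away from the dense regime
#' (f != 0.5), where H0 depends on the evolving weight spread.
#'
#' @inheritParams learningThresholds
#' @param eta learning rate; default 0.01 (0.001 when `eps == 0`).
#' @param maxSweeps sweep budget; default 1000 (10000 when `eps == 0`).
#' @param recalibrateH0 recalibrate H0 after each sweep; default `f != 0.5`.
#' @return A [LearningConfig-class].
#' @export
learningConfig <- function(params, eps, gamma = params@gamma,
                           eta = if (eps == 0) 0.001 else 0.01,
                           maxSweeps = if (eps == 0) 10000L else 1000L,
                           recalibrateH0 = params@f != 0.5) {
  th <- learningThresholds(params, eps, gamma)
  new("LearningConfig", eta = eta, eps = eps, gamma = gamma,
      theta0 = as.numeric(th["theta0"]), theta1 = as.numeric(th["theta1"]),
      maxSweeps = as.integer(maxSweeps), recalibrateH0 = recalibrateH0)
}

setMethod("show", "LearningConfig", function(object) {
  cat(sprintf(paste0("LearningConfig: eta = %g, eps = %g, gamma = %g,\n",
                     "  theta0 = %.3f, theta1 = %.3f, maxSweeps = %d, ",
                     "recalibrateH0 = %s\n"),
              object@eta, object@eps, object@gamma, object@theta0,
              object@theta1, object@maxSweeps, object@recalibrateH0))
  invisible(NULL)
})

#' One application of the three-threshold plasticity rule
#'
#' For every postsynaptic neuron i, depending on its local field v_i:
#' depression (w_ij decreased by eta*s_j) when theta0 < v_i < theta,
#' potentiation (increased by eta*s_j) when theta < v_i < theta1, and no
#' plasticity when the field lies below theta0 or above theta1. All intervals
#' are open (a field exactly at a threshold produces no change). Weights are
#' clipped at zero (excitatory sign constraint) and the diagonal stays zero.
#'
#' @param W a [WeightMatrix-class] or numeric matrix.
#' @param presynState 0/1 vector of presynaptic states s.
#' @param fields numeric vector of local fields v (computed in the clamped
#'   condition, i.e. with the pattern applied).
#' @param params a [NetworkParams-class].
#' @param config a [LearningConfig-class].
#' @return A [WeightMatrix-class].
#' @export
threeThresholdUpdate <- function(W, presynState, fields, params, config) {
  Wm <- asWeightMat(W)
  d <- numeric(nrow(Wm))
  d[fields > config@theta0 & fields < params@theta] <- -config@eta
  d[fields > params@theta & fields < config@theta1] <- config@eta
  active <- which(presynState == 1)
  if (length(active) && any(d != 0)) {
    Wm[, active] <- pmax(Wm[, active] + d, 0)
    diag(Wm) <- 0
  }
  new("WeightMatrix", W = Wm)
}

#' Present one pattern and apply the learning rule once
#'
#' The training step for a single pattern: the pattern is applied as a strong
#' external field x = X*xi, one synchronous update is performed (for
#' sufficiently strong gamma this clamps the state to the pattern), the local
#' fields are recomputed in the clamped condition, and the three-threshold
#' update is applied with the clamped state as the presynaptic input.
#'
#' @inheritParams threeThresholdUpdate
#' @param pattern 0/1 vector, the pattern xi.
#' @param state 0/1 vector, the network state before presentation; defaults
#'   to the pattern-free all-zero state.
#' @return A list with `weights` (a [WeightMatrix-class]) and `state` (the
#'   post-presentation network state).
#' @export
presentAndLearn <- function(W, pattern, params, config,
                            state = integer(params@N)) {
  x <- params@X * pattern
  sNew <- stepNetwork(W, state, x, params)
  v <- localFields(W, sNew, x, params)
  list(weights = threeThresholdUpdate(W, sNew, v, params, config),
       state = sNew)
}

trainInternal <- function(W, patternSet, params, config, seed, rule) {
  Wm <- asWeightMat(W)
  Xi <- patterns(patternSet)
  stopIfNot(ncol(Xi) == nrow(Wm) || nPatterns(patternSet) == 0L,
            "pattern width must match the network size")
  res <- withSeed(seed, {
    s0 <- as.integer(runif(nrow(Wm)) < params@f)
    cppTrain(Wm, Xi, as.integer(rule), params@f, params@theta, params@psi,
             params@H0, params@H1, params@lambda, params@X,
             config@eta, config@eps, config@theta0, config@theta1,
             config@maxSweeps, config@recalibrateH0,
             qnorm(params@f, lower.tail = FALSE), params@lambda, s0)
  })
  new("TrainingResult", weights = new("WeightMatrix", W = res$W),
      sweepsUsed = as.integer(res$sweepsUsed), converged = res$converged,
      errorsPerSweep = as.numeric(res$errorsPerSweep),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Train a network with the three-threshold rule
#'
#' Presents the patterns sequentially, in a fresh random permutation per
#' sweep; each presentation follows the [presentAndLearn()] scheme (the
#' network state carries over between presentations). After each full sweep
#' the robust fixed-point condition (margin f*eps*sqrt(N)) is checked for
#' every pattern with zero external field, and training stops as soon as no
#' violations remain. When `config@recalibrateH0` is set (sparse regime), H0
#' is recomputed from the current weight statistics after every sweep.
#'
#' @param W initial weights ([WeightMatrix-class]).
#' @param patternSet a [PatternSet-class].
#' @param params a [NetworkParams-class].
#' @param config a [LearningConfig-class].
#' @param seed optional integer seed controlling the initial state and the
#'   presentation order.
#' @return A [TrainingResult-class].
#' @examples
#' par <- networkParams(101, f = 0.5, gamma = 6)
#' W <- initializeWeights(101, seed = 1)
#' fit <- train3TLR(W, generatePatterns(101, 10, 0.5, seed = 2), par,
#'                  learningConfig(par, eps = 1), seed = 3)
#' fit@converged
#' @export
train3TLR <- function(W, patternSet, params, config, seed = NULL)
  trainInternal(W, patternSet, params, config, seed, rule = 0L)

#' Train with the supervised perceptron rule (baseline)
#'
#' Identical protocol to [train3TLR()] — same presentation scheme, same
#' pseudo-random choices under a shared seed, same stopping rule — except the
#' plasticity step: the desired output is read from the pattern, the actual
#' output from the margin test on the clamped local field (v > theta1 for ON
#' units, v < theta0 for OFF units), and active synapses are changed by
#' +/- eta on error. At strong external drive the two rules coincide exactly;
#' at moderate gamma the 3TLR occasionally misreads the desired output and
#' the two weight trajectories diverge.
#'
#' @inheritParams train3TLR
#' @return A [TrainingResult-class].
#' @export
trainPLR <- function(W, patternSet, params, config, seed = NULL)
  trainInternal(W, patternSet, params, config, seed, rule = 1L)

setMethod("show", "TrainingResult", function(object) {
  cat(sprintf("TrainingResult: %s after %d sweep(s); final errors = %d\n",
              if (object@converged) "converged" else "NOT converged",
              object@sweepsUsed,
              if (length(object@errorsPerSweep))
                as.integer(tail(object@errorsPerSweep, 1L)) else 0L))
  invisible(NULL)
})

#' @rdname accessors
#' @export
setMethod("weights", "TrainingResult", function(object, ...) object@weights@W)

#' Count robust fixed-point violations
#'
#' Number of per-neuron constraint violations over all patterns: with the
#' state clamped at each pattern and zero external field, an ON unit must
#' have v > theta + f*eps*sqrt(N) and an OFF unit v < theta - f*eps*sqrt(N).
#'
#' @inheritParams train3TLR
#' @param eps robustness margin used in the check.
#' @return Integer violation count (0 means every pattern is a robust fixed
#'   point).
#' @export
countViolations <- function(W, patternSet, params, eps = 0) {
  cppCountErrors(asWeightMat(W), patterns(patternSet), params@H0,
                 params@lambda, params@theta, params@f, eps)
}
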