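#' @import methods
NULL

#' Binary memory pattern sets
#'
#' A set of p binary patterns over N units at coding level f (the probability
#' that an entry is 1). Optionally carries a category structure: L prototype
#' patterns and, for every pattern, the index of the category it was generated
#' from together with the pattern-prototype correlation c.
#'
#' @slot patterns integer matrix, p x N, entries in \{0, 1\}; one pattern per row.
#' @slot codingLevel numeric in (0, 1); the coding level f.
#' @slot categoryOf integer vector of length p (or length 0 when the set has no
#'   category structure) giving the category index of each pattern.
#' @slot prototypes integer matrix, L x N, the category prototypes (0 rows when
#'   the set has no category structure).
#' @slot correlation numeric, the target pattern-prototype correlation c
#'   (length 0 when the set has no category structure).
#' @seealso [generatePatterns()], [generateCategorizedPatterns()]
#' @export
setClass("PatternSet",
  representation(patterns = "matrix", codingLevel = "numeric",
                 categoryOf = "integer", prototypes = "matrix",
                 correlation = "numeric"),
  prototype(patterns = matrix(integer(), 0L, 0L), codingLevel = 0.5,
            categoryOf = integer(), prototypes = matrix(integer(), 0L, 0L),
            correlation = numeric()))

setValidity("PatternSet", function(object) {
  p <- object@patterns
  if (length(p) && !all(p %in% c(0L, 1L)))
    return("pattern entries must all be 0 or 1")
  f <- object@codingLevel
  if (length(f) != 1L || f <= 0 || f >= 1)
    return("codingLevel must be a single value in (0, 1)")
  if (length(object@categoryOf)) {
    if (length(object@categoryOf) != nrow(p))
      return("categoryOf must have one entry per pattern")
    if (!nrow(object@prototypes))
      return("categorized sets must carry their prototypes")
    if (length(unique(object@categoryOf)) != nrow(object@prototypes))
      return("number of prototypes must equal the number of distinct categories")
    if (ncol(object@prototypes) != ncol(p))
      return("prototypes and patterns must have the same number of units")
  }
  TRUE
})

#' Non-negative recurrent weight matrix
#'
#' The recurrent synaptic matrix W of the excitatory network: entries w_ij
#' (weight of the synapse from neuron j onto neuron i) are continuous,
#' non-negative, with zero self-connections.
#'
#' @slot W numeric N x N matrix, entries >= 0, zero diagonal.
#' @seealso [initializeWeights()], [meanWeight()], [sdWeight()]
#' @export
setClass("WeightMatrix", representation(W = "matrix"))

setValidity("WeightMatrix", function(object) {
  W <- object@W
  if (nrow(W) != ncol(W)) return("W must be square")
  if (nrow(W) < 2L) return("W must be at least 2 x 2")
  if (any(W < 0)) return("all weights must be non-negative")
  if (any(diag(W) != 0)) return("the diagonal (self-connections) must be exactly 0")
  TRUE
})

#' Network and inhibition parameters
#'
#' Scalar parameters of the binary recurrent network: size N, target activity
#' level f, neuronal threshold theta = (N-1) psi, inhibitory feedback slope
#' lambda, external-field scale gamma (field strength X = gamma sqrt(N)), and
#' the inhibition calibration terms H0 (basal inhibition) and H1 (inhibitory
#' reaction to the external input).
#'
#' @slot N integer, number of excitatory units.
#' @slot f numeric in (0,1), spontaneous activity level / pattern coding level.
#' @slot theta numeric, neuronal threshold; equal to (N-1)*psi.
#' @slot psi numeric, per-synapse threshold scale.
#' @slot lambda numeric, slope of the linear inhibitory feedback.
#' @slot gamma numeric >= 0, external-field scale.
#' @slot X numeric, external field strength 2*f*gamma*sqrt(N)
#'   (= gamma*sqrt(N) in the dense regime f = 0.5).
#' @slot H0,H1 numeric, inhibition calibration terms (see [deriveInhibition()]).
#' @seealso [networkParams()]
#' @export
setClass("NetworkParams",
  representation(N = "integer", f = "numeric", theta = "numeric",
                 psi = "numeric", lambda = "numeric", gamma = "numeric",
                 X = "numeric", H0 = "numeric", H1 = "numeric"))

setValidity("NetworkParams", function(object) {
  if (object@N < 2L) return("N must be >= 2")
  if (object@f <= 0 || object@f >= 1) return("f must be in (0, 1)")
  if (object@gamma < 0) return("gamma must be >= 0")
  if (abs(object@theta - (object@N - 1L) * object@psi) >
      1e-8 * max(1, abs(object@theta)))
    return("theta must equal (N-1)*psi")
  TRUE
})

#' Learning configuration
#'
#' Parameters of the training protocol shared by the three-threshold rule and
#' the perceptron-rule baseline: learning rate eta, robustness margin eps, the
#' external-field scale gamma used during training, the two auxiliary learning
#' thresholds theta0 = theta - (gamma+eps) f sqrt(N) and
#' theta1 = theta + (gamma+eps) f sqrt(N), the sweep budget, and whether H0 is
#' recalibrated from the current weight statistics after each sweep.
#'
#' @slot eta numeric > 0, learning rate.
#' @slot eps numeric >= 0, robustness parameter.
#' @slot gamma numeric, external-field scale used during training.
#' @slot theta0,theta1 numeric, lower/upper learning thresholds.
#' @slot maxSweeps integer, maximum number of full passes over the pattern set.
#' @slot recalibrateH0 logical, recompute H0 after each sweep (needed when
#'   f != 0.5, where H0 depends on the evolving weight standard deviation).
#' @seealso [learningConfig()], [train3TLR()], [trainPLR()]
#' @export
setClass("LearningConfig",
  representation(eta = "numeric", eps = "numeric", gamma = "numeric",
                 theta0 = "numeric", theta1 = "numeric", maxSweeps = "integer",
                 recalibrateH0 = "logical"))

setValidity("LearningConfig", function(object) {
  if (object@eta < 0) return("eta must be >= 0")
  if (object@eps < 0) return("eps must be >= 0")
  if (object@maxSweeps < 1L) return("maxSweeps must be >= 1")
  if (!(object@theta0 <= object@theta1)) return("theta0 must be <= theta1")
  TRUE
})

#' Training result
#'
#' @slot weights [WeightMatrix-class], the trained weights.
#' @slot sweepsUsed integer, sweeps performed before stopping.
#' @slot converged logical, TRUE when every pattern satisfied the robust
#'   fixed-point condition (zero errors) at the last sweep.
#' @slot errorsPerSweep numeric vector, number of violated per-neuron
#'   constraints after each sweep.
#' @slot seed integer, seed used for the presentation order (NA if none given).
#' @export
setClass("TrainingResult",
  representation(weights = "WeightMatrix", sweepsUsed = "integer",
                 converged = "logical", errorsPerSweep = "numeric",
                 seed = "integer"))

setValidity("TrainingResult", function(object) {
  if (object@converged && length(object@errorsPerSweep) &&
      tail(object@errorsPerSweep, 1L) != 0)
    return("a converged result must end with zero errors")
  TRUE
})

#' Basin-of-attraction measurement result
#'
#' @slot basinFraction numeric, the largest perturbation fraction b at which
#'   the pattern set is successfully stored (all per-pattern retrieval rates
#'   >= 0.9), or 0 if none.
#' @slot rates numeric, per-pattern retrieval rates at `basinFraction`.
#' @slot nTrials integer, number of noisy trials per pattern.
#' @slot success logical, whether the criterion held at `basinFraction`.
#' @slot details data.frame, one row per (pattern, b) evaluated.
#' @export
setClass("RetrievalResult",
  representation(basinFraction = "numeric", rates = "numeric",
                 nTrials = "integer", success = "logical",
                 details = "data.frame"))

setValidity("RetrievalResult", function(object) {
  r <- object@rates
  if (length(r) && (any(r < 0) || any(r > 1))) return("rates must lie in [0, 1]")
  if (length(r) && object@success != (min(r) >= 0.9))
    return("success flag must equal (min rate >= 0.9)")
  TRUE
})

#' Storage-capacity curve
#'
#' Monte-Carlo estimate of the probability of successful storage as a function
#' of the load alpha = p/N.
#'
#' @slot alphaGrid numeric, evaluated loads.
#' @slot successProb numeric, estimated success probability at each load.
#' @slot nSeeds integer, replicates per load.
#' @slot details data.frame, one row per (alpha, seed).
#' @seealso [capacityCurve()], [alphaAt()]
#' @export
setClass("CapacityCurve",
  representation(alphaGrid = "numeric", successProb = "numeric",
                 nSeeds = "integer", details = "data.frame"))

setValidity("CapacityCurve", function(object) {
  if (length(object@alphaGrid) != length(object@successProb))
    return("alphaGrid and successProb must have equal length")
  if (length(object@successProb) &&
      (any(object@successProb < 0) || any(object@successProb > 1)))
    return("successProb must lie in [0, 1]")
  TRUE
})

#' Replica-symmetric critical-capacity solution
#'
#' Order parameters of the critical-capacity saddle-point system for the
#' sign-constrained perceptron problem solved by each neuron, at coding level
#' f and reduced robustness K = eps / wbar.
#'
#' @slot f,K numeric, problem parameters.
#' @slot T numeric, threshold coefficient Hinv(f)*sqrt(f).
#' @slot alphaC numeric, critical capacity (patterns per neuron).
#' @slot Q,A,B,C,M numeric, saddle-point order parameters (Q = relative weight
#'   variance (sigma_w/wbar)^2 at criticality; M = rescaled mean order
#'   parameter; A, B, C = divergence coefficients of the conjugate parameters).
#' @slot residual numeric, maximum absolute equation residual at the solution.
#' @slot degenerate logical, TRUE for the K = 0 branch (Q -> 0, where the
#'   sign constraint becomes irrelevant and the Gardner bound is recovered).
#' @export
setClass("SaddleSolution",
  representation(f = "numeric", K = "numeric", T = "numeric",
                 alphaC = "numeric", Q = "numeric", A = "numeric",
                 B = "numeric", C = "numeric", M = "numeric",
                 residual = "numeric", degenerate = "logical"))

setValidity("SaddleSolution", function(object) {
  if (!is.finite(object@alphaC) || object@alphaC <= 0)
    return("alphaC must be positive and finite")
  if (object@residual > 1e-8) return("residual must be <= 1e-8")
  if (object@Q < 0) return("Q must be >= 0")
  if (!object@degenerate && (object@A <= 0 || object@A >= 1))
    return("A must lie in (0, 1) away from the degenerate branch")
  TRUE
})

#' Replica-symmetric entropy saddle solution (below capacity)
#'
#' Order parameters extremizing the quenched entropy of the solution volume at
#' load alpha < alpha_c: self-overlap Q, mutual overlap q, rescaled mean M and
#' the conjugate parameters, together with the entropy S.
#'
#' @slot f,K,alpha numeric, problem parameters.
#' @slot Q,q,M numeric, order parameters (0 <= q <= Q).
#' @slot qHat,dQHat,MHat numeric, conjugate order parameters
#'   (dQHat = qHat - 2*QHat).
#' @slot entropy numeric, the entropy S at the saddle.
#' @slot residual numeric, maximum absolute equation residual.
#' @export
setClass("EntropySolution",
  representation(f = "numeric", K = "numeric", alpha = "numeric",
                 Q = "numeric", q = "numeric", M = "numeric",
                 qHat = "numeric", dQHat = "numeric", MHat = "numeric",
                 entropy = "numeric", residual = "numeric"))

setValidity("EntropySolution", function(object) {
  if (object@q < -1e-10 || object@q > object@Q + 1e-10)
    return("q must lie in [0, Q]")
  if (!is.finite(object@entropy)) return("entropy must be finite")
  TRUE
})
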