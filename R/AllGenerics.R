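#' Accessors for tlrnet classes
#'
#' Small accessor generics: `patterns()` returns the p x N binary matrix of a
#' [PatternSet-class]; `nPatterns()` / `nUnits()` its dimensions;
#' `codingLevel()` its coding level f; `weights()` the numeric matrix inside a
#' [WeightMatrix-class] or [TrainingResult-class]; `meanWeight()` /
#' `sdWeight()` the mean and standard deviation of the off-diagonal entries
#' (the quantities wbar and sigma_w entering the inhibition calibration);
#' `alphaAt()` the interpolated load at a given success probability of a
#' [CapacityCurve-class].
#'
#' @param object an object of the documented classes.
#' @param q success probability at which to interpolate the load.
#' @return See each generic's description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("patterns", function(object) standardGeneric("patterns"))
#' @rdname accessors
#' @export
setGeneric("nPatterns", function(object) standardGeneric("nPatterns"))
#' @rdname accessors
#' @export
setGeneric("nUnits", function(object) standardGeneric("nUnits"))
#' @rdname accessors
#' @export
setGeneric("codingLevel", function(object) standardGeneric("codingLevel"))
#' @rdname accessors
#' @export
setGeneric("weights", function(object, ...) standardGeneric("weights"))
#' @rdname accessors
#' @export
setGeneric("meanWeight", function(object) standardGeneric("meanWeight"))
#' @rdname accessors
#' @export
setGeneric("sdWeight", function(object) standardGeneric("sdWeight"))
#' @rdname accessors
#' @export
setGeneric("alphaAt", function(object, q = 0.5) standardGeneric("alphaAt"))

#' Fraction of silent synapses
#'
#' Fraction of off-diagonal weights at (or numerically below) zero. Training
#' at capacity drives a finite fraction of excitatory synapses exactly to the
#' zero bound ("silent" or "potential" synapses), and this fraction grows
#' with the robustness parameter. Clipping during learning produces exact
#' zeros, so the default tolerance is 0.
#'
#' @param object a [WeightMatrix-class], [TrainingResult-class] or matrix.
#' @param tol weights <= tol count as silent (default 0).
#' @return Fraction in [0, 1].
#' @export
setGeneric("silentFraction", function(object, tol = 0)
  standardGeneric("silentFraction"))

#' Symmetry degree of the weight matrix
#'
#' Pearson correlation between reciprocal weights w_ij and w_ji over
#' unordered off-diagonal pairs (i < j). Hebbian matrices are exactly
#' symmetric (r = 1); random matrices give r near 0; networks trained near
#' capacity become increasingly symmetric as the load grows.
#'
#' @param object a [WeightMatrix-class], [TrainingResult-class] or matrix.
#' @return Pearson correlation in [-1, 1].
#' @export
setGeneric("symmetryDegree", function(object) standardGeneric("symmetryDegree"))
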