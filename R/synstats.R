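#' @rdname silentFraction
#' @export
setMethod("silentFraction", "ANY", function(object, tol = 0) {
  W <- asWeightMat(object)
  mean(W[offDiag(W)] <= tol)
})

#' @rdname symmetryDegree
#' @export
setMethod("symmetryDegree", "ANY", function(object) {
  W <- asWeightMat(object)
  stopIfNot(nrow(W) >= 3L, "need at least 3 units")
  up <- upper.tri(W)
  cor(W[up], t(W)[up])
})

#' Histogram of the nonzero weights
#'
#' Fixed-bin-width density of the strictly positive weights (the silent
#' synapses at exactly zero are reported separately through
#' [silentFraction()]). After training at capacity this distribution
#' resembles a truncated Gaussian whose mode shifts toward zero as the
#' robustness parameter grows.
#'
#' @inheritParams silentFraction
#' @param binWidth histogram bin width (default 0.05).
#' @param nonzeroOnly drop the exact zeros before binning (default TRUE).
#' @return data.frame with columns `mid` (bin midpoint) and `density`.
#' @export
weightHistogram <- function(object, binWidth = 0.05, nonzeroOnly = TRUE) {
  W <- asWeightMat(object)
  w <- W[offDiag(W)]
  if (nonzeroOnly) w <- w[w > 0]
  breaks <- seq(0, max(w) + binWidth, by = binWidth)
  h <- hist(w, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, density = h$density)
}

#' @importFrom graphics hist
NULL
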