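#' Generate random binary memory patterns
#'
#' Draws `nPatterns` binary patterns over `nUnits` units; each entry is 1
#' independently with probability `codingLevel` (Bernoulli coding, so the
#' number of active units fluctuates around f*N from pattern to pattern).
#' A master `seed` deterministically spawns one independent sub-stream per
#' pattern, so generating a larger set with the same seed reproduces the
#' earlier patterns bit for bit.
#'
#' @param nUnits number of units N (>= 2).
#' @param nPatterns number of patterns p (>= 0).
#' @param codingLevel coding level f in (0, 1).
#' @param seed optional integer master seed; NULL uses the current RNG stream.
#' @return A [PatternSet-class].
#' @examples
#' ps <- generatePatterns(100, 10, 0.5, seed = 1)
#' mean(patterns(ps))
#' @export
generatePatterns <- function(nUnits, nPatterns, codingLevel, seed = NULL) {
  stopIfNot(is.numeric(nUnits) && nUnits >= 2, "nUnits must be >= 2")
  stopIfNot(is.numeric(nPatterns) && nPatterns >= 0, "nPatterns must be >= 0")
  stopIfNot(is.numeric(codingLevel) && length(codingLevel) == 1L &&
            codingLevel > 0 && codingLevel < 1,
            "codingLevel must lie strictly inside (0, 1)")
  nUnits <- as.integer(nUnits); nPatterns <- as.integer(nPatterns)
  xi <- matrix(0L, nPatterns, nUnits)
  if (nPatterns > 0L) {
    if (is.null(seed)) {
      xi[] <- as.integer(runif(nPatterns * nUnits) < codingLevel)
    } else {
      for (mu in seq_len(nPatterns))
        xi[mu, ] <- withSeed(deriveSeed(seed, mu),
                             as.integer(runif(nUnits) < codingLevel))
    }
  }
  new("PatternSet", patterns = xi, codingLevel = codingLevel)
}

#' Generate category-correlated binary patterns
#'
#' Draws L prototype patterns at coding level f, then for each category
#' generates `patternsPerCategory` patterns by copying each prototype entry
#' with probability c and otherwise resampling it Bernoulli(f) independently.
#' This construction has Pearson correlation exactly c between a pattern and
#' its prototype (for any f), preserves the coding level, and yields
#' within-category pattern-pair correlation c^2 and zero between-category
#' correlation in expectation.
#'
#' @inheritParams generatePatterns
#' @param nCategories number of categories L (>= 1).
#' @param patternsPerCategory patterns generated per category.
#' @param correlation pattern-prototype correlation c in [0, 1].
#' @return A [PatternSet-class] with category structure.
#' @export
generateCategorizedPatterns <- function(nUnits, nCategories, patternsPerCategory,
                                        codingLevel, correlation, seed = NULL) {
  stopIfNot(is.numeric(correlation) && length(correlation) == 1L &&
            correlation >= 0 && correlation <= 1,
            "correlation must lie in [0, 1]")
  stopIfNot(is.numeric(nCategories) && nCategories >= 1, "nCategories must be >= 1")
  L <- as.integer(nCategories)
  proto <- generatePatterns(nUnits, L, codingLevel, seed = seed)
  nUnits <- as.integer(nUnits)
  p <- L * as.integer(patternsPerCategory)
  xi <- matrix(0L, p, nUnits)
  catOf <- rep(seq_len(L), each = as.integer(patternsPerCategory))
  genOne <- function(g) {
    keep <- runif(nUnits) < correlation
    ifelse(keep, patterns(proto)[g, ], as.integer(runif(nUnits) < codingLevel))
  }
  for (mu in seq_len(p)) {
    g <- catOf[mu]
    xi[mu, ] <- if (is.null(seed)) genOne(g) else
      withSeed(deriveSeed(seed, L + mu), genOne(g))
  }
  new("PatternSet", patterns = xi, codingLevel = codingLevel,
      categoryOf = as.integer(catOf), prototypes = patterns(proto),
      correlation = correlation)
}

#' @rdname accessors
#' @export
setMethod("patterns", "PatternSet", function(object) object@patterns)
#' @rdname accessors
#' @export
setMethod("nPatterns", "PatternSet", function(object) nrow(object@patterns))
#' @rdname accessors
#' @export
setMethod("nUnits", "PatternSet", function(object) ncol(object@patterns))
#' @rdname accessors
#' @export
setMethod("codingLevel", "PatternSet", function(object) object@codingLevel)

setMethod("show", "PatternSet", function(object) {
  cat(sprintf("PatternSet: %d patterns x %d units, coding level f = %g\n",
              nPatterns(object), nUnits(object), codingLevel(object)))
  if (length(object@categoryOf))
    cat(sprintf("  categorized: L = %d categories, prototype correlation c = %g\n",
                nrow(object@prototypes), object@correlation))
  if (nPatterns(object) > 0L)
    cat(sprintf("  empirical activation frequency: %.4f\n",
                mean(object@patterns)))
  invisible(NULL)
})

#' Plain-text serialization of pattern sets
#'
#' `writePatterns()` writes one pattern per line as a string of '0'/'1'
#' characters (with a small '#'-prefixed header holding the coding level and
#' any category structure); `readPatterns()` reads it back. The round trip is
#' lossless.
#'
#' @param object a [PatternSet-class].
#' @param file path to the text file.
#' @return `readPatterns()` returns a [PatternSet-class]; `writePatterns()`
#'   returns `file` invisibly.
#' @export
writePatterns <- function(object, file) {
  stopIfNot(is(object, "PatternSet"), "object must be a PatternSet")
  con <- file(file, "w"); on.exit(close(con))
  writeLines(sprintf("# codingLevel %.17g", object@codingLevel), con)
  if (length(object@correlation))
    writeLines(sprintf("# correlation %.17g", object@correlation), con)
  if (length(object@categoryOf))
    writeLines(paste("# categoryOf", paste(object@categoryOf, collapse = " ")), con)
  if (nrow(object@prototypes))
    for (g in seq_len(nrow(object@prototypes)))
      writeLines(paste0("#proto ", paste(object@prototypes[g, ], collapse = "")), con)
  if (nPatterns(object) > 0L)
    writeLines(apply(object@patterns, 1L, paste, collapse = ""), con)
  invisible(file)
}

#' @rdname writePatterns
#' @export
readPatterns <- function(file) {
  lines <- readLines(file)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  parseBits <- function(s)
    as.integer(strsplit(s, "", fixed = TRUE)[[1L]])
  getMeta <- function(key) {
    hit <- grep(paste0("^# ", key, " "), meta, value = TRUE)
    if (!length(hit)) return(NULL)
    strsplit(sub(paste0("^# ", key, " "), "", hit[1L]), " ")[[1L]]
  }
  f <- as.numeric(getMeta("codingLevel"))
  xi <- if (length(body)) do.call(rbind, lapply(body, parseBits)) else
    matrix(integer(), 0L, 0L)
  protoLines <- grep("^#proto ", meta, value = TRUE)
  proto <- if (length(protoLines))
    do.call(rbind, lapply(sub("^#proto ", "", protoLines), parseBits)) else
    matrix(integer(), 0L, 0L)
  catOf <- getMeta("categoryOf")
  corr <- getMeta("correlation")
  new("PatternSet", patterns = xi, codingLevel = f,
      categoryOf = if (is.null(catOf)) integer() else as.integer(catOf),
      prototypes = proto,
      correlation = if (is.null(corr)) numeric() else as.numeric(corr))
}
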