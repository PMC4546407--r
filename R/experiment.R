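## Reproduction-oriented experiment front end: flat key=value configs, tidy
## tab-separated results, deterministic given the seed. A thin command-line
## wrapper over runExperiment() ships in inst/scripts/tlrnet.R.

#' Read and write flat key=value experiment configurations
#'
#' The configuration format is one `key=value` pair per line (lists as
#' comma-separated values, '#' comments allowed) — diff-able and language
#' neutral. Defaults for unspecified network parameters equal the
#' dense-regime simulation column: N = 1001, f = 0.5, psi = 0.35, gamma = 6,
#' eta = 0.01, 1000 sweeps, 50 test trials.
#'
#' @param file path to the config file.
#' @return `readExperimentConfig()` returns a named list.
#' @export
readExperimentConfig <- function(file) {
  lines <- readLines(file)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    stopIfNot(length(kv) == 2L, sprintf("malformed config line: '%s'", ln))
    key <- trimws(kv[1L])
    vals <- trimws(strsplit(kv[2L], ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(vals))
    cfg[[key]] <- if (all(!is.na(num))) num else vals
  }
  cfg
}

#' @rdname readExperimentConfig
#' @param config named list of configuration values.
#' @export
writeExperimentConfig <- function(config, file) {
  lines <- vapply(names(config), function(k)
    paste0(k, "=", paste(format(config[[k]], digits = 17, trim = TRUE),
                         collapse = ",")),
    character(1L))
  writeLines(lines, file)
  invisible(file)
}

experimentDefaults <- function() {
  list(N = 1001, f = 0.5, psi = 0.35, gamma = 6, eps = 0.3, b = 0,
       sweeps = NA, trials = 50, nSeeds = 10, seed = 1)
}

configHash <- function(config) {
  config <- config[order(names(config))]
  txt <- paste(vapply(names(config), function(k)
    paste0(k, "=", paste(format(config[[k]], digits = 17), collapse = ",")),
    character(1L)), collapse = ";")
  ## 31-bit polynomial rolling hash over the canonical text, printed as hex
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run a named experiment and write its artifacts
#'
#' Dispatches to one of the package's experiment protocols and writes a tidy
#' tab-separated result table, a config snapshot, and a short run log to
#' `outDir`. Every output embeds the config hash and package version, and an
#' identical configuration (including the seed) reproduces identical result
#' files.
#'
#' Available experiments: `capacity` (success probability over a load grid),
#' `basin` (basin size of one trained pattern set), `gamma-sweep`, `eps-opt`,
#' `compare-rules`, `hopfield-baseline` (breakdown load of the Hebbian
#' network), `theory` (critical-capacity table over eps), and `stats`
#' (connectivity statistics of one trained network).
#'
#' @param config named list (see [readExperimentConfig()]); must contain
#'   `experiment`, other fields default to the dense-regime values.
#' @param outDir output directory (created if missing); NULL skips writing.
#' @return The result data.frame, invisibly when writing.
#' @export
runExperiment <- function(config, outDir = NULL) {
  stopIfNot(!is.null(config$experiment), "config must name an 'experiment'")
  cfg <- experimentDefaults()
  for (k in names(config)) cfg[[k]] <- config[[k]]
  kind <- as.character(cfg$experiment)
  seed <- as.integer(cfg$seed)
  alphaGrid <- if (!is.null(cfg$alphaGrid)) cfg$alphaGrid else
    seq(0.2, 1.6, by = 0.2)
  sweeps <- if (is.na(cfg$sweeps[1L])) NULL else as.integer(cfg$sweeps)

  res <- switch(kind,
    "capacity" = {
      cc <- capacityCurve(cfg$N, cfg$eps, cfg$gamma, cfg$f, cfg$b, alphaGrid,
                          nSeeds = cfg$nSeeds, seed = seed,
                          psi = cfg$psi, nTrials = cfg$trials,
                          maxSweeps = sweeps)
      data.frame(alpha = cc@alphaGrid, successProb = cc@successProb)
    },
    "basin" = {
      p <- max(1L, round(cfg$alpha * cfg$N))
      ps <- generatePatterns(cfg$N, p, cfg$f, seed = deriveSeed(seed, 1L))
      W0 <- initializeWeights(cfg$N, seed = deriveSeed(seed, 2L))
      par <- networkParams(cfg$N, f = cfg$f, psi = cfg$psi, gamma = cfg$gamma,
                           meanW = meanWeight(W0), sdW = sdWeight(W0))
      lc <- learningConfig(par, eps = cfg$eps)
      if (!is.null(sweeps)) lc@maxSweeps <- sweeps
      fit <- train3TLR(W0, ps, par, lc, seed = deriveSeed(seed, 3L))
      bs <- basinSize(fit@weights, ps, par, nTrials = cfg$trials,
                      seed = deriveSeed(seed, 4L))
      bs@details
    },
    "gamma-sweep" = gammaSweep(cfg$N, cfg$f, cfg$eps,
                               gammaGrid = cfg$gammaGrid,
                               alphaGrid = alphaGrid, seed = seed,
                               psi = cfg$psi, nTrials = cfg$trials,
                               maxSweeps = sweeps),
    "eps-opt" = optimizeOverEps(cfg$N, cfg$gamma, cfg$f, cfg$b,
                                epsGrid = cfg$epsGrid, alphaGrid = alphaGrid,
                                nSeeds = cfg$nSeeds, seed = seed,
                                psi = cfg$psi, nTrials = cfg$trials,
                                maxSweeps = sweeps)$table,
    "compare-rules" = compareRules(cfg$N, cfg$f, cfg$eps, cfg$gamma,
                                   alphaGrid, nSamples = cfg$nSeeds,
                                   seed = seed, psi = cfg$psi,
                                   maxSweeps = sweeps),
    "hopfield-baseline" = {
      hl <- hopfieldCriticalLoad(cfg$N, nSeeds = cfg$nSeeds, seed = seed)
      hl$details
    },
    "theory" = theoryCurve(cfg$f, epsGrid = if (!is.null(cfg$epsGrid))
      cfg$epsGrid else c(0, 0.3, 0.6, 1, 2, 3)),
    "stats" = {
      p <- max(1L, round(cfg$alpha * cfg$N))
      ps <- generatePatterns(cfg$N, p, cfg$f, seed = deriveSeed(seed, 1L))
      W0 <- initializeWeights(cfg$N, seed = deriveSeed(seed, 2L))
      par <- networkParams(cfg$N, f = cfg$f, psi = cfg$psi, gamma = cfg$gamma,
                           meanW = meanWeight(W0), sdW = sdWeight(W0))
      lc <- learningConfig(par, eps = cfg$eps)
      if (!is.null(sweeps)) lc@maxSweeps <- sweeps
      fit <- train3TLR(W0, ps, par, lc, seed = deriveSeed(seed, 3L))
      data.frame(silentFraction = silentFraction(fit),
                 symmetryDegree = symmetryDegree(fit),
                 meanWeight = meanWeight(fit@weights),
                 sdWeight = sdWeight(fit@weights),
                 converged = fit@converged)
    },
    stop(sprintf("unknown experiment '%s'", kind), call. = FALSE))

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    hash <- configHash(cfg)
    ver <- as.character(utils::packageVersion("tlrnet"))
    stamp <- sprintf("# tlrnet %s | experiment %s | config %s | seed %d",
                     ver, kind, hash, seed)
    resFile <- file.path(outDir, sprintf("%s-%s.tsv", kind, hash))
    con <- file(resFile, "w")
    writeLines(stamp, con)
    suppressWarnings(write.table(res, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
    close(con)
    writeExperimentConfig(cfg[!vapply(cfg, is.null, logical(1L))],
                          file.path(outDir, sprintf("%s-%s.config", kind, hash)))
    writeLines(c(stamp, format(Sys.time(), "# finished %Y-%m-%d %H:%M:%S")),
               file.path(outDir, sprintf("%s-%s.log", kind, hash)))
    return(invisible(res))
  }
  res
}

#' Plain-text serialization of weight matrices
#'
#' Tab-separated text with a '#'-prefixed metadata header (package version
#' plus any supplied parameters); the round trip preserves the weights to
#' full double precision.
#'
#' @param object a [WeightMatrix-class] or [TrainingResult-class].
#' @param file output path.
#' @param metadata optional named list written into the header.
#' @return `readWeights()` returns a [WeightMatrix-class].
#' @export
writeWeights <- function(object, file, metadata = list()) {
  W <- asWeightMat(object)
  con <- file(file, "w"); on.exit(close(con))
  writeLines(sprintf("# tlrnet %s WeightMatrix %d",
                     as.character(utils::packageVersion("tlrnet")), nrow(W)), con)
  for (k in names(metadata))
    writeLines(paste0("# ", k, " ", paste(format(metadata[[k]], digits = 17),
                                          collapse = " ")), con)
  write.table(format(W, digits = 17, trim = TRUE, scientific = TRUE), con,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname writeWeights
#' @export
readWeights <- function(file) {
  lines <- readLines(file)
  body <- lines[!startsWith(lines, "#")]
  W <- do.call(rbind, lapply(strsplit(body, "\t", fixed = TRUE), as.numeric))
  new("WeightMatrix", W = W)
}
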