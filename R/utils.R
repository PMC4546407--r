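#' @importFrom stats dnorm pnorm qnorm rnorm runif quantile cor sd approx optimize uniroot optim
#' @importFrom utils write.table read.table head tail
NULL

## Run an expression under a given seed without clobbering the caller's RNG
## stream; seed = NULL means "use the current stream".
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## Deterministically derive a sub-stream seed from a master seed and an index.
## Lehmer-style mixing mod 2^31-1 keeps results in valid set.seed() range and
## makes stream k independent of how many streams precede it, so pattern sets
## are extendable without changing earlier patterns.
deriveSeed <- function(master, k) {
  m <- 2147483647
  s <- ((as.double(master) %% m) * 48271 + as.double(k) * 16807 + 12345) %% m
  as.integer(s %% (m - 1L)) + 1L
}

stopIfNot <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
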