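## Replica-symmetric storage-capacity theory for the sign-constrained
## perceptron problem solved by each neuron.
##
## Per-neuron constraint (weights reparametrized as W_j = w_j/wbar - 1 in
## [-1, Inf), K = eps/wbar, T = Hinv(f) sqrt(f)):
##     sigma^mu ( sum_j W_j xi_j^mu - T (sigma_w/wbar) sqrt(N) ) > f K sqrt(N).
## Averaging over Bernoulli(f) patterns and normalizing the Gaussian field by
## its standard deviation sqrt(f(1-f) N Q) gives the reduced margin
##     kappa = K sqrt(f/(1-f)),
## the reduced threshold coefficient Ttil = Hinv(f)/sqrt(1-f) (multiplying
## sqrt(Q)), and the rescaled mean order parameter m. At f = 0.5 both
## kappa = K and Ttil = 0, so the dense-regime results do not depend on this
## normalization choice. All Gaussian integrals use >= 200-node Gauss-Hermite
## quadrature; H, G and the Mills ratio are evaluated in log space so the
## solvers stay stable for arguments up to |x| ~ 40.

#' Gaussian special functions
#'
#' The Gaussian density G(x) = exp(-x^2/2)/sqrt(2*pi), the tail function
#' H(x) = erfc(x/sqrt(2))/2 and the inverse Mills ratio
#' calG(x) = G(x)/H(x), all evaluated stably for large |x| (log-space
#' evaluation, accurate up to |x| ~ 40).
#'
#' @param x numeric vector.
#' @return A list with components `G`, `H`, `calG`.
#' @examples
#' gaussianFuncs(0)     # H = 0.5, G = 0.3989
#' @export
gaussianFuncs <- function(x) {
  list(G = dnorm(x), H = hTail(x), calG = millsRatio(x))
}

hTail <- function(x) pnorm(x, lower.tail = FALSE)
lnHTail <- function(x) pnorm(x, lower.tail = FALSE, log.p = TRUE)
hTailInv <- function(f) qnorm(f, lower.tail = FALSE)
millsRatio <- function(x) exp(dnorm(x, log = TRUE) - lnHTail(x))

## int Du f(u) with Du the standard Gaussian measure.
ghNodes <- local({
  cache <- NULL
  function(n = 201L) {
    if (is.null(cache)) {
      gh <- pracma::gaussHermite(n)
      cache <<- list(u = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
    }
    cache
  }
})

## sigma-average <phi(sigma)> = f phi(+1) + (1-f) phi(-1) applied to the two
## tau values tau(+1), tau(-1).
sigAvg <- function(f, phiPlus, phiMinus) f * phiPlus + (1 - f) * phiMinus

## E[(t - tau)^2 ; t > tau] for t ~ N(0,1): the Gardner integral.
brFun <- function(tau) (1 + tau^2) * hTail(tau) - tau * dnorm(tau)
## E[(t - tau)   ; t > tau]
e1Fun <- function(tau) dnorm(tau) - tau * hTail(tau)

tauSigma <- function(Q, m, kappa, Ttil) {
  mt <- m - Ttil * sqrt(Q)
  c(plus = (mt - kappa) / sqrt(Q), minus = (-mt - kappa) / sqrt(Q))
}

## Degenerate K = 0 branch: Q -> 0 shrinks the sign constraint away and the
## capacity equals the unconstrained Gardner value at coding level f:
## alpha_c = 1 / <br(sigma a)> with the offset a solving <sigma e1(sigma a)> = 0.
degenerateCapacity <- function(f) {
  g <- function(a) f * e1Fun(a) - (1 - f) * e1Fun(-a)
  a <- if (f == 0.5) 0 else uniroot(g, c(-15, 15), tol = 1e-14)$root
  den <- sigAvg(f, brFun(a), brFun(-a))
  list(alphaC = 1 / den, a = a, residual = abs(g(a)))
}

## Residuals of the critical-capacity system at x = (log Q, m, log alpha).
## Given (Q, m, alpha): A and C follow from their defining equations, u_c and
## B from A = H(u_c) with u_c = B - A/sqrt(C); the remaining three equations
## (the sigma-stationarity, and the two conditions obtained as the
## DeltaQ -> 0 limit of the conjugate-side saddle equations) are returned.
criticalResiduals <- function(x, f, kappa, Ttil) {
  Q <- exp(x[1L]); m <- x[2L]; alpha <- exp(x[3L])
  if (!all(is.finite(c(Q, m, alpha)))) return(rep(1e6, 3L))
  tau <- tauSigma(Q, m, kappa, Ttil)
  A <- alpha * sigAvg(f, hTail(tau[1L]), hTail(tau[2L]))
  C <- alpha * Q * sigAvg(f, brFun(tau[1L]), brFun(tau[2L]))
  if (!is.finite(A) || !is.finite(C) || A <= 0 || A >= 1 || C <= 0)
    return(rep(1e6, 3L))
  uc <- hTailInv(A)
  B <- uc + A / sqrt(C)
  r1 <- f * e1Fun(tau[1L]) - (1 - f) * e1Fun(tau[2L])
  r2 <- (sqrt(C) / A) * (dnorm(uc) - B * A) - (1 - A)
  r3 <- Q - (1 - A) -
    (C * (1 + B^2) * A - (B * C + A * sqrt(C)) * dnorm(uc)) / A^2
  c(r1, r2, r3)
}

## Damped Newton with a numerical Jacobian (central differences); step is
## halved until the residual norm decreases.
dampedNewton <- function(resFun, x0, tol = 1e-11, maxIter = 200L) {
  resFun0 <- resFun
  resFun <- function(x) {
    r <- resFun0(x)
    r[!is.finite(r)] <- 1e6
    r
  }
  x <- x0
  r <- resFun(x)
  for (it in seq_len(maxIter)) {
    if (max(abs(r)) < tol) break
    n <- length(x)
    J <- matrix(0, length(r), n)
    h <- pmax(1e-7, 1e-7 * abs(x))
    for (j in seq_len(n)) {
      xp <- x; xp[j] <- x[j] + h[j]
      xm <- x; xm[j] <- x[j] - h[j]
      J[, j] <- (resFun(xp) - resFun(xm)) / (2 * h[j])
    }
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lam <- 1
    repeat {
      xNew <- x - lam * step
      rNew <- resFun(xNew)
      if (sum(rNew^2) < sum(r^2) || lam < 1e-6) break
      lam <- lam / 2
    }
    if (max(abs(xNew - x)) < 1e-15) { x <- xNew; r <- rNew; break }
    x <- xNew; r <- rNew
  }
  list(x = x, residual = max(abs(r)))
}

solveCriticalAtK <- function(f, K, guess = NULL) {
  kappa <- K * sqrt(f / (1 - f))
  Ttil <- hTailInv(f) / sqrt(1 - f)
  deg <- degenerateCapacity(f)
  resFun <- function(x) criticalResiduals(x, f, kappa, Ttil)
  starts <- list()
  if (!is.null(guess)) starts[[1L]] <- guess
  ## multistart around the degenerate solution: tau_sigma ~ sigma*a - s with
  ## s = kappa/sqrt(Q), so Q = (kappa/s)^2 and m ~ (a + Ttil) sqrt(Q)
  for (s in c(0.2, 0.5, 1, 1.5, 2, 3))
    for (afrac in c(0.95, 0.8, 0.6, 0.4)) {
      Q <- (kappa / s)^2
      m <- (deg$a + Ttil) * sqrt(Q)
      starts[[length(starts) + 1L]] <- c(log(Q), m, log(afrac * deg$alphaC))
    }
  best <- NULL
  for (x0 in starts) {
    r0 <- resFun(x0)
    if (max(abs(r0)) >= 1e6) next
    sol <- dampedNewton(resFun, x0)
    if (sol$residual < 1e-9) { best <- sol; break }
    if (is.null(best) || sol$residual < best$residual) best <- sol
  }
  if (is.null(best) || best$residual > 1e-8) {
    ## polish via least squares before giving up
    x0 <- if (is.null(best)) starts[[1L]] else best$x
    op <- optim(x0, function(x) sum(resFun(x)^2),
                control = list(maxit = 5000, reltol = 1e-16))
    sol <- dampedNewton(resFun, op$par)
    if (is.null(best) || sol$residual < best$residual) best <- sol
  }
  if (best$residual > 1e-8)
    stop(sprintf(
      "critical-capacity solver did not converge at f = %g, K = %g (last residual %.3g)",
      f, K, best$residual), call. = FALSE)
  x <- best$x
  Q <- exp(x[1L]); m <- x[2L]; alpha <- exp(x[3L])
  tau <- tauSigma(Q, m, kappa, Ttil)
  A <- alpha * sigAvg(f, hTail(tau[1L]), hTail(tau[2L]))
  C <- alpha * Q * sigAvg(f, brFun(tau[1L]), brFun(tau[2L]))
  B <- hTailInv(A) + A / sqrt(C)
  list(alphaC = alpha, Q = Q, A = A, B = B, C = C, M = m,
       residual = best$residual, x = x)
}

#' Critical capacity from the replica-symmetric saddle point
#'
#' Solves the critical-capacity system of the sign-constrained perceptron at
#' coding level f and reduced robustness K = eps/wbar. At K = 0 the system
#' has a degenerate branch (Q -> 0) on which the sign constraint becomes
#' irrelevant and the capacity equals the unconstrained Gardner value —
#' exactly 2 at f = 0.5, larger at sparser coding. For K > 0 the full
#' six-parameter system is solved by damped Newton iteration with
#' continuation in K from the degenerate limit; non-convergence raises an
#' error (never a silent wrong answer).
#'
#' @param f coding level in (0, 1).
#' @param K reduced robustness parameter (>= 0).
#' @return A [SaddleSolution-class].
#' @examples
#' alphaC(criticalCapacity(0.5, 0))    # the Gardner bound, 2
#' @export
criticalCapacity <- function(f, K) {
  stopIfNot(f > 0 && f < 1, "f must be in (0, 1)")
  stopIfNot(K >= 0, "K must be >= 0")
  Trep <- hTailInv(f) * sqrt(f)
  if (K == 0) {
    deg <- degenerateCapacity(f)
    return(new(Class = "SaddleSolution", f = f, K = 0, T = Trep,
               alphaC = deg$alphaC, Q = 0, A = 1, B = 0, C = 0, M = deg$a,
               residual = deg$residual, degenerate = TRUE))
  }
  ## continuation upward in K
  Ks <- seq(min(0.05, K), K, length.out = max(2L, ceiling(K / 0.1) + 1L))
  Ks[length(Ks)] <- K
  guess <- NULL
  for (Kk in Ks) {
    sol <- solveCriticalAtK(f, Kk, guess = guess)
    guess <- sol$x
  }
  new(Class = "SaddleSolution", f = f, K = K, T = Trep, alphaC = sol$alphaC,
      Q = sol$Q, A = sol$A, B = sol$B, C = sol$C, M = sol$M,
      residual = sol$residual, degenerate = FALSE)
}

#' @rdname criticalCapacity
#' @param object a [SaddleSolution-class].
#' @export
alphaC <- function(object) object@alphaC

setMethod("show", "SaddleSolution", function(object) {
  cat(sprintf(paste0("SaddleSolution (f = %g, K = %g%s): alpha_c = %.6f\n",
                     "  Q = %.4g, A = %.4g, B = %.4g, C = %.4g, M = %.4g, ",
                     "residual = %.2g\n"),
              object@f, object@K,
              if (object@degenerate) ", degenerate branch" else "",
              object@alphaC, object@Q, object@A, object@B, object@C,
              object@M, object@residual))
  invisible(NULL)
})

## ---- general (below-capacity) entropy saddle ----

truncMoments <- function(a, b) {
  mu <- b / a; s <- 1 / sqrt(a)
  z <- -(1 + mu) * sqrt(a)           # standardized truncation point W = -1
  lam <- millsRatio(z)
  EW <- mu + s * lam
  EW2 <- mu^2 + s^2 + s * lam * (mu - 1)
  list(EW = EW, EW2 = EW2, z = z)
}

entropyResiduals <- function(x, f, kappa, Ttil, alpha, quad) {
  Q <- exp(x[1L]); dQ <- exp(x[2L]); m <- x[3L]
  qh <- exp(x[4L]); ah <- exp(x[5L]); Mh <- x[6L]
  q <- Q - dQ
  if (!all(is.finite(c(Q, dQ, m, qh, ah, Mh, q))) || q <= 0)
    return(rep(1e6, 6L))
  u <- quad$u; w <- quad$w
  mt <- m - Ttil * sqrt(Q)
  tp <- (kappa - mt + u * sqrt(q)) / sqrt(dQ)
  tm <- (kappa + mt + u * sqrt(q)) / sqrt(dQ)
  Gp <- millsRatio(tp); Gm <- millsRatio(tm)
  I1 <- sum(w * u * (f * Gp + (1 - f) * Gm))
  I2 <- sum(w * (f * Gp * tp + (1 - f) * Gm * tm))
  I3 <- sum(w * (f * Gp - (1 - f) * Gm))
  tm2 <- truncMoments(ah, u * sqrt(qh) - Mh)
  J0 <- sum(w * tm2$EW)
  J1 <- sum(w * u * tm2$EW)
  J2 <- sum(w * tm2$EW2)
  ## residuals scaled by each equation's magnitude (qHat and dQHat diverge as
  ## DeltaQ -> 0, so absolute residuals would be meaningless there)
  r <- c((ah - alpha * I1 / sqrt(q * dQ)) / ah,
         (qh - ah - alpha * I2 / dQ) / qh,
         I3,
         (Q - J2) / Q,
         (dQ - J1 / sqrt(qh)) / dQ,
         J0)
  r[!is.finite(r)] <- 1e6
  r
}

#' Entropy saddle point below capacity
#'
#' Solves the full replica-symmetric saddle system for the quenched entropy
#' of the solution volume at load alpha below the critical capacity:
#' order parameters (Q, q, M) and conjugates (qHat, dQHat, MHat), by damped
#' Newton iteration started from the critical-capacity solution. Gaussian
#' integrals use 201-node Gauss-Hermite quadrature. As alpha approaches the
#' critical capacity the overlap gap DeltaQ = Q - q closes; extrapolating
#' DeltaQ -> 0 reproduces [criticalCapacity()]'s alpha_c, which serves as an
#' internal consistency check between the two independent solvers.
#'
#' @inheritParams criticalCapacity
#' @param alpha load, strictly below the critical capacity at (f, K).
#' @param guess optional list with starting values (elements Q, dQ, M, qHat,
#'   dQHat, MHat), e.g. a previous solution at a nearby alpha.
#' @return An [EntropySolution-class].
#' @export
entropySaddle <- function(f, K, alpha, guess = NULL) {
  stopIfNot(f > 0 && f < 1, "f must be in (0, 1)")
  stopIfNot(K >= 0 && alpha > 0, "K must be >= 0 and alpha > 0")
  kappa <- K * sqrt(f / (1 - f))
  Ttil <- hTailInv(f) / sqrt(1 - f)
  quad <- ghNodes()
  crit <- if (K > 0) {
    cc <- criticalCapacity(f, K)
    list(alphaC = cc@alphaC, Q = cc@Q, A = cc@A, B = cc@B, C = cc@C, M = cc@M)
  } else {
    ## start from a small-K critical solution; the K = 0 branch is degenerate
    cc <- criticalCapacity(f, 1e-3)
    list(alphaC = cc@alphaC, Q = cc@Q, A = cc@A, B = cc@B, C = cc@C, M = cc@M)
  }
  stopIfNot(alpha < crit$alphaC,
            "alpha must lie below the critical capacity for this (f, K)")
  resFun <- function(x) entropyResiduals(x, f, kappa, Ttil, alpha, quad)
  starts <- list()
  if (!is.null(guess))
    starts[[1L]] <- c(log(guess$Q), log(guess$dQ), guess$M,
                      log(guess$qHat), log(guess$dQHat), guess$MHat)
  for (frac in c(0.3, 0.15, 0.5, 0.05)) {
    dQ0 <- frac * crit$Q * max(0.05, 1 - alpha / crit$alphaC + 0.05)
    starts[[length(starts) + 1L]] <-
      c(log(crit$Q), log(dQ0), crit$M,
        log(crit$C / dQ0^2), log(crit$A / dQ0),
        crit$B * sqrt(crit$C) / dQ0)
  }
  best <- NULL
  for (x0 in starts) {
    if (max(abs(resFun(x0))) >= 1e6) next
    sol <- dampedNewton(resFun, x0, tol = 1e-10)
    if (is.null(best) || sol$residual < best$residual) best <- sol
    if (best$residual < 1e-9) break
  }
  if ((is.null(best) || best$residual > 1e-8) && is.null(guess) &&
      alpha / crit$alphaC > 0.82) {
    ## continuation in alpha: walk up from well below capacity, where the
    ## critical-solution starting point is reliable, chaining solutions
    path <- unique(c(seq(0.80, alpha / crit$alphaC, by = 0.01),
                     alpha / crit$alphaC)) * crit$alphaC
    sol <- NULL
    for (aa in path) {
      g <- if (is.null(sol)) NULL else
        list(Q = sol@Q, dQ = sol@Q - sol@q, M = sol@M, qHat = sol@qHat,
             dQHat = sol@dQHat, MHat = sol@MHat)
      sol <- tryCatch(entropySaddle(f, K, aa, guess = g),
                      error = function(e) NULL)
      if (is.null(sol)) break
    }
    if (!is.null(sol) && abs(sol@alpha - alpha) < 1e-12)
      best <- list(x = c(log(sol@Q), log(sol@Q - sol@q), sol@M,
                         log(sol@qHat), log(sol@dQHat), sol@MHat),
                   residual = sol@residual)
  }
  if (is.null(best) || best$residual > 1e-8)
    stop(sprintf(
      "entropy-saddle solver did not converge at f = %g, K = %g, alpha = %g",
      f, K, alpha), call. = FALSE)
  x <- best$x
  Q <- exp(x[1L]); dQ <- exp(x[2L]); m <- x[3L]
  qh <- exp(x[4L]); ah <- exp(x[5L]); Mh <- x[6L]
  S <- entropyValue(Q, dQ, m, qh, ah, Mh, f, kappa, Ttil, alpha, quad)
  new("EntropySolution", f = f, K = K, alpha = alpha, Q = Q, q = Q - dQ,
      M = m, qHat = qh, dQHat = ah, MHat = Mh, entropy = S,
      residual = best$residual)
}

entropyValue <- function(Q, dQ, m, qh, ah, Mh, f, kappa, Ttil, alpha, quad) {
  u <- quad$u; w <- quad$w
  q <- Q - dQ
  Qh <- (qh - ah) / 2                # from dQHat = qHat - 2*QHat
  mt <- m - Ttil * sqrt(Q)
  tp <- (kappa - mt + u * sqrt(q)) / sqrt(dQ)
  tm <- (kappa + mt + u * sqrt(q)) / sqrt(dQ)
  ZA <- sum(w * (f * lnHTail(tp) + (1 - f) * lnHTail(tm)))
  b <- u * sqrt(qh) - Mh
  z <- -(1 + b / ah) * sqrt(ah)
  lnZin <- b^2 / (2 * ah) + 0.5 * log(2 * pi / ah) + lnHTail(z)
  ZW <- sum(w * lnZin)
  -(Q * Qh - q * qh / 2) + alpha * ZA + ZW
}

setMethod("show", "EntropySolution", function(object) {
  cat(sprintf(paste0("EntropySolution (f = %g, K = %g, alpha = %g):\n",
                     "  Q = %.5g, q = %.5g (DeltaQ = %.3g), M = %.4g, ",
                     "S = %.5g, residual = %.2g\n"),
              object@f, object@K, object@alpha, object@Q, object@q,
              object@Q - object@q, object@M, object@entropy, object@residual))
  invisible(NULL)
})

#' Capacity estimate from the entropy solver
#'
#' Solves the entropy saddle at a sequence of loads and extrapolates the
#' closing of the overlap gap DeltaQ(alpha) -> 0 linearly to estimate the
#' critical capacity independently of [criticalCapacity()].
#'
#' @inheritParams entropySaddle
#' @param alphas loads at which to solve (increasing, below alpha_c); by
#'   default fractions 0.97, 0.985 and 0.995 of the critical solver's
#'   alpha_c, close enough that the linear extrapolation error is below 1e-3.
#' @return A list with `alphaC` (the extrapolated capacity), `alphas` and
#'   `deltaQ` (the gaps at the evaluated loads).
#' @export
entropyCapacityEstimate <- function(f, K, alphas = NULL) {
  if (is.null(alphas)) {
    ac <- alphaC(criticalCapacity(f, K))
    alphas <- c(0.97, 0.985, 0.995) * ac
  }
  dq <- numeric(length(alphas))
  for (i in seq_along(alphas)) {
    sol <- entropySaddle(f, K, alphas[i])
    dq[i] <- sol@Q - sol@q
  }
  fit <- stats::lm.fit(cbind(1, dq), alphas)
  list(alphaC = as.numeric(fit$coefficients[1L]), alphas = alphas,
       deltaQ = dq)
}

#' Theoretical capacity as a function of the robustness parameter
#'
#' Maps eps to the reduced robustness K = eps/wbar and evaluates the critical
#' capacity along the grid, optionally also returning the unconstrained-
#' weights Gardner capacity at the same margins for comparison (the gap
#' between the two curves is the price of the excitatory sign constraint).
#'
#' @param f coding level.
#' @param epsGrid robustness values.
#' @param meanW mean synaptic weight wbar used in K = eps/wbar (default: the
#'   rectified-Gaussian initialization mean, 1.0833, which stays essentially
#'   constant during learning).
#' @return data.frame with columns `eps`, `K`, `alphaC`.
#' @export
theoryCurve <- function(f = 0.5, epsGrid, meanW = rectifiedMoments()["mean"]) {
  meanW <- as.numeric(meanW)
  rows <- lapply(epsGrid, function(e) {
    sol <- criticalCapacity(f, e / meanW)
    data.frame(eps = e, K = e / meanW, alphaC = alphaC(sol))
  })
  do.call(rbind, rows)
}
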