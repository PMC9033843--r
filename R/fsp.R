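# Finite state projection of the single-cell birth-death model and the
# Bayesian measurement filter built on it.
#
# The chemical master equation on copy numbers {0..N} is truncated with an
# absorbing sink state collecting the probability that leaks past N; the
# propagator is the matrix exponential of the (N+2)x(N+2) generator
# (birth rate b0 + k*u, death rate gamma*n). Probability is conserved:
# sum(p) + leaked == 1 between measurement updates.

# internal: augmented generator (column convention: dp/dt = A p), sink last
fspGenerator <- function(N, birth, gamma) {
  n <- N + 2L
  A <- matrix(0, n, n)
  for (s in 0:N) {
    i <- s + 1L
    out <- 0
    if (s < N) { A[i + 1L, i] <- birth; out <- out + birth }
    else { A[n, i] <- birth; out <- out + birth }       # leak past N
    if (s > 0) { A[i - 1L, i] <- gamma * s; out <- out + gamma * s }
    A[i, i] <- -out
  }
  A
}

#' Precompute FSP transition kernels for one measurement interval
#'
#' Matrix exponentials of the truncated generator for the light-off and
#' light-on birth rates. One pair serves every cell and every candidate
#' profile of a single-cell control run, which keeps 100-cell experiments
#' tractable.
#'
#' @param params a [GeneExpressionParams-class].
#' @param N truncation bound.
#' @param dtMin interval length (min).
#' @return list with elements `off` and `on`, (N+2)x(N+2) dense matrices.
#' @export
fspKernels <- function(params, N, dtMin) {
  k0 <- as.matrix(Matrix::expm(Matrix::Matrix(
    fspGenerator(N, params@b0, params@gamma) * dtMin)))
  k1 <- as.matrix(Matrix::expm(Matrix::Matrix(
    fspGenerator(N, params@b0 + params@k, params@gamma) * dtMin)))
  list(off = k0, on = k1)
}

#' Propagate an FSP state over one measurement interval
#'
#' Applies `expm(A * dt)` to the augmented distribution, with the birth rate
#' set by the delayed activation read from the head of the input buffer.
#' Boundary outflow accumulates in `leaked`. The buffer is shifted with the
#' light decision applied now (unless `dtMin == 0`, which is a no-op).
#'
#' @param state an [FspState-class].
#' @param appliedLight logical light decision applied at this step.
#' @param dtMin interval length (min).
#' @param params a [GeneExpressionParams-class].
#' @param kernels optional precomputed [fspKernels()] for this `dtMin`.
#' @return updated [FspState-class].
#' @export
fspPropagate <- function(state, appliedLight, dtMin, params, kernels = NULL) {
  if (dtMin < 0) stop("dtMin must be >= 0")
  if (dtMin == 0) return(state)
  u <- state@inputBuffer[1]
  N <- state@N
  statMean <- (params@b0 + params@k) / params@gamma
  if (N < statMean + 5 * sqrt(statMean))
    warning("FSP truncation bound N = ", N,
            " is below the stationary mean + 5 SD; leakage likely")
  Tm <- if (!is.null(kernels)) {
    if (u >= 0.5) kernels$on else kernels$off
  } else {
    as.matrix(Matrix::expm(Matrix::Matrix(
      fspGenerator(N, params@b0 + params@k * u, params@gamma) * dtMin)))
  }
  aug <- as.numeric(Tm %*% c(state@p, state@leaked))
  new("FspState", N = N, p = pmax(aug[seq_len(N + 1L)], 0),
      leaked = aug[N + 2L],
      inputBuffer = c(state@inputBuffer[-1], as.numeric(appliedLight)))
}

#' Condition an FSP state on a fluorescence measurement
#'
#' Bayesian update with Gaussian likelihood `y ~ N(alpha * n, sigmaMeas^2)`;
#' the posterior is renormalised to sum to one and the leaked mass is reset.
#' If the measurement is incompatible with the whole support (more than 10
#' SD from every state), the prior is kept and a warning raised.
#'
#' @param state an [FspState-class].
#' @param measurement fluorescence (a.u.).
#' @param params a [GeneExpressionParams-class].
#' @return updated [FspState-class].
#' @export
fspUpdate <- function(state, measurement, params) {
  if (sum(state@p) <= 0) stop("fspUpdate needs sum(p) > 0")
  ns <- 0:state@N
  z <- abs(measurement - params@alpha * ns) / params@sigmaMeas
  if (min(z[state@p > 0]) > 10) {
    warning("measurement ", signif(measurement, 5),
            " incompatible with FSP support; keeping prior")
    p <- state@p / sum(state@p)
  } else {
    w <- state@p * stats::dnorm(measurement, params@alpha * ns,
                                params@sigmaMeas)
    if (sum(w) <= 0) {
      warning("zero posterior mass; keeping prior")
      p <- state@p / sum(state@p)
    } else p <- w / sum(w)
  }
  new("FspState", N = state@N, p = p, leaked = 0,
      inputBuffer = state@inputBuffer)
}

#' Central credible interval of an FSP state
#'
#' @param state an [FspState-class].
#' @param level credible level (default 0.9).
#' @return integer vector `c(lo, hi)` in copy-number units.
#' @export
fspCredibleInterval <- function(state, level = 0.9) {
  p <- state@p / sum(state@p)
  cdf <- cumsum(p)
  a <- (1 - level) / 2
  lo <- which(cdf >= a)[1] - 1L
  hi <- which(cdf >= 1 - a)[1] - 1L
  c(lo = lo, hi = hi)
}

#' Re-initialise a daughter cell's FSP state at division
#'
#' Molecules partition binomially at division, so the daughter distribution
#' is the binomial thinning (q = 0.5 for an even split) of the parent's.
#'
#' @param state parent [FspState-class].
#' @param q retention probability.
#' @return daughter [FspState-class].
#' @export
fspDivide <- function(state, q = 0.5) {
  N <- state@N
  p <- numeric(N + 1L)
  for (n in 0:N) {
    if (state@p[n + 1L] == 0) next
    kk <- 0:n
    p[kk + 1L] <- p[kk + 1L] + state@p[n + 1L] * stats::dbinom(kk, n, q)
  }
  new("FspState", N = N, p = p, leaked = state@leaked,
      inputBuffer = state@inputBuffer)
}
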