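# Controllers: constant-step adaptive exposure regulation, and receding-
# horizon model predictive control of gene expression.
#
# The MPC enumerates all 2^H binary pulse sequences over the horizon. The
# production delay tau means an input chosen now takes effect only
# D = ceil(tau/step) intervals later, so the estimate is first rolled
# forward D steps on the already-committed input buffer and each candidate
# is scored against the target over the window where it actually acts
# (steps t+D+1 .. t+D+H). Without this shift every candidate would yield
# the same predicted trajectory inside a 24-min horizon and the controller
# could never act.

#' One step of the constant-step adaptive exposure controller
#'
#' If the measured mean fluorescence is below `target - deadband`, the
#' exposure is increased by `step` ms; above `target + deadband`, decreased;
#' otherwise unchanged. The result is clamped to `[eMin, eMax]`.
#'
#' @param measuredMean measured mean cell fluorescence (a.u.).
#' @param currentExposure current exposure (ms).
#' @param params an [ExposureControllerParams-class].
#' @return new exposure (ms).
#' @export
exposureStep <- function(measuredMean, currentExposure, params) {
  e <- currentExposure
  if (measuredMean < params@target - params@deadband) e <- e + params@step
  else if (measuredMean > params@target + params@deadband) e <- e - params@step
  min(max(e, params@eMin), params@eMax)
}

#' All binary candidate profiles of a horizon
#'
#' Rows are ordered lexicographically with "off" before "on" and the first
#' step most significant, so earlier rows use less light earlier; this
#' ordering is the deterministic tie-break of the controllers.
#'
#' @param H horizon length (steps).
#' @return logical matrix `2^H x H`.
#' @export
candidateProfiles <- function(H) {
  stopifnot(H >= 1)
  n <- 2^H
  m <- matrix(FALSE, n, H)
  for (j in seq_len(H))
    m[, j] <- bitwAnd(0:(n - 1), bitwShiftL(1L, H - j)) > 0L
  m
}

#' Target value at an absolute step index
#'
#' The target profile is extended by its last value past its end.
#'
#' @param task a [ControlTask-class].
#' @param step 1-based step index.
#' @return target fluorescence (a.u.).
#' @export
targetAt <- function(task, step) {
  r <- task@targetProfile
  r[pmin(pmax(step, 1L), length(r))]
}

# internal: pick argmin with ties broken toward less total light, then
# lexicographically-off-first (= lower row index of candidateProfiles)
pickCandidate <- function(costs, profiles) {
  o <- order(costs, rowSums(profiles), seq_len(nrow(profiles)))
  o[1]
}

#' Population-level MPC step (deterministic model, squared-error cost)
#'
#' Rolls the Kalman mean forward over the committed delay buffer, then
#' scores every candidate binary profile by the sum of squared deviations
#' between the predicted fluorescence and the target over the window the
#' candidate inputs act on, and returns the first step of the minimiser.
#'
#' @param est a [KalmanState-class].
#' @param task a [ControlTask-class].
#' @param params a [GeneExpressionParams-class].
#' @param currentStep 0-based index of the current measurement step.
#' @return list: `apply` (logical first decision), `profile` (logical vector
#'   of length H), `cost`.
#' @export
mpcSelectDeterministic <- function(est, task, params, currentStep = 0L) {
  H <- task@horizonSteps
  D <- length(est@inputBuffer)
  m <- est@mean
  for (d in seq_len(D))
    m <- meanStep(m, est@inputBuffer[d], params, task@stepMin)
  profiles <- candidateProfiles(H)
  r <- targetAt(task, currentStep + D + seq_len(H))
  costs <- numeric(nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    mm <- m; cost <- 0
    for (h in seq_len(H)) {
      mm <- meanStep(mm, as.numeric(profiles[i, h]), params, task@stepMin)
      cost <- cost + (params@alpha * mm - r[h])^2
    }
    costs[i] <- cost
  }
  best <- pickCandidate(costs, profiles)
  list(apply = profiles[best, 1], profile = profiles[best, ],
       cost = costs[best])
}

#' Single-cell MPC step (FSP model, expected-absolute-deviation cost)
#'
#' As [mpcSelectDeterministic()], but the prediction is the full FSP
#' distribution and the cost is `sum_h E|alpha*n - r_h|` under the predictive
#' distribution. Candidate prefixes are shared through a depth-first tree so
#' each distinct prefix is propagated once. If the predictive mass is
#' non-finite or fully leaked the all-off profile is returned.
#'
#' @param est an [FspState-class].
#' @param task a [ControlTask-class].
#' @param params a [GeneExpressionParams-class].
#' @param kernels precomputed [fspKernels()] for `task@stepMin`.
#' @param currentStep 0-based current measurement step.
#' @return list: `apply`, `profile`, `cost`.
#' @export
mpcSelectSingleCell <- function(est, task, params, kernels = NULL,
                                currentStep = 0L) {
  if (is.null(kernels)) kernels <- fspKernels(params, est@N, task@stepMin)
  H <- task@horizonSteps
  D <- length(est@inputBuffer)
  p <- c(est@p, est@leaked)
  for (d in seq_len(D)) {
    Tm <- if (est@inputBuffer[d] >= 0.5) kernels$on else kernels$off
    p <- as.numeric(Tm %*% p)
  }
  r <- targetAt(task, currentStep + D + seq_len(H))
  ns <- 0:est@N
  alpha <- params@alpha
  profiles <- candidateProfiles(H)
  costs <- rep(NA_real_, nrow(profiles))
  # depth-first over the binary tree; row index reconstruction uses the
  # lexicographic layout of candidateProfiles
  walk <- function(pvec, h, idx0, acc) {
    for (bit in c(0L, 1L)) {
      Tm <- if (bit) kernels$on else kernels$off
      pn <- as.numeric(Tm %*% pvec)
      ead <- sum(pn[seq_along(ns)] * abs(alpha * ns - r[h]))
      acc2 <- acc + ead
      idx <- idx0 + bit * 2^(H - h)
      if (h == H) costs[idx + 1L] <<- acc2
      else walk(pn, h + 1L, idx, acc2)
    }
  }
  walk(p, 1L, 0L, 0)
  if (any(!is.finite(costs)) || sum(p) <= 1e-12) {
    return(list(apply = FALSE, profile = rep(FALSE, H), cost = NA_real_,
                fallback = TRUE))
  }
  best <- pickCandidate(costs, profiles)
  list(apply = profiles[best, 1], profile = profiles[best, ],
       cost = costs[best])
}

#' Expected absolute deviation of a discrete fluorescence distribution
#'
#' @param p probability vector over copy numbers `0:(length(p)-1)`.
#' @param alpha fluorescence units per molecule.
#' @param r target fluorescence.
#' @return `E|alpha*n - r|`.
#' @export
expectedAbsDeviation <- function(p, alpha, r) {
  n <- seq_along(p) - 1
  sum(p * abs(alpha * n - r))
}

#' Precompute an open-loop light profile on the model
#'
#' Runs the receding-horizon optimisation entirely on the deterministic
#' model (no measurements): at each step the current model state selects the
#' best candidate profile, its first decision is committed and the model is
#' advanced. The concatenated decisions form the profile applied identically
#' to all cells.
#'
#' @param params a [GeneExpressionParams-class].
#' @param task a [ControlTask-class].
#' @param totalSteps number of measurement steps to plan.
#' @param p0 initial protein level (molecules).
#' @return a [LightProfile-class] of length `totalSteps`.
#' @export
precomputeOpenLoop <- function(params, task, totalSteps, p0 = 0) {
  stopifnot(totalSteps >= task@horizonSteps)
  st <- KalmanState(mean = p0, variance = 0, params = params,
                    stepMin = task@stepMin)
  pulses <- logical(totalSteps)
  for (t in seq_len(totalSteps)) {
    sel <- mpcSelectDeterministic(st, task, params, currentStep = t - 1L)
    pulses[t] <- sel$apply
    st <- kalmanStep(st, appliedLight = sel$apply, measurement = NULL,
                     params = params, stepMin = task@stepMin, q = 0)
  }
  LightProfile(pulses, stepMin = task@stepMin, pulseMs = task@pulseMs)
}

#' Time-averaged deviation to target
#'
#' The control performance metric: the mean over time of the absolute (or
#' squared) difference between the measured output and its target.
#'
#' @param measured numeric vector of measurements.
#' @param target numeric vector (recycled) of targets.
#' @param type `"absolute"` or `"squared"`.
#' @return scalar performance (0 when the trajectory equals the target).
#' @export
controlPerformance <- function(measured, target, type = "absolute") {
  type <- match.arg(type, c("absolute", "squared"))
  d <- measured - rep_len(target, length(measured))
  if (type == "absolute") mean(abs(d)) else mean(d^2)
}
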