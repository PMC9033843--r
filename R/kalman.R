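# Kalman filtering for the population ("average cell") model.
#
# The state is the scalar protein level; the input delay is handled by a
# buffer of the activations applied over the last tau minutes (input
# augmentation). Prediction uses the exact discretisation of
# dP/dt = b0 + k u - gamma P over one measurement interval; the default
# process noise is the exact conditional variance of the underlying
# birth-death process over the interval (binomial survival + Poisson
# production), i.e. the linear-noise increment.

# internal: exact one-step mean propagation in molecule units
meanStep <- function(m, u, params, dtMin) {
  a <- exp(-params@gamma * dtMin)
  a * m + (params@b0 + params@k * u) * (1 - a) / params@gamma
}

#' One predict(+update) step of the Kalman filter
#'
#' Predicts over one measurement interval using the delayed activation read
#' from the head of the input buffer, then (if a measurement is given)
#' applies the standard linear-Gaussian update with measurement model
#' `y = alpha * P + N(0, sigmaMeas^2)`. The buffer is shifted with the light
#' decision applied at this step.
#'
#' @param state a [KalmanState-class].
#' @param appliedLight logical, light decision applied now (enters the
#'   buffer; takes effect after the delay).
#' @param measurement fluorescence measurement (a.u.) or `NULL`.
#' @param params a [GeneExpressionParams-class].
#' @param stepMin measurement interval (min).
#' @param q process-noise variance for the step; `NULL` uses the exact
#'   birth-death conditional variance.
#' @return updated [KalmanState-class].
#' @export
kalmanStep <- function(state, appliedLight, measurement = NULL, params,
                       stepMin = 6, q = NULL) {
  u <- state@inputBuffer[1]
  a <- exp(-params@gamma * stepMin)
  b <- params@b0 + params@k * u
  mPred <- meanStep(state@mean, u, params, stepMin)
  if (is.null(q))
    q <- a * (1 - a) * max(state@mean, 0) + (b / params@gamma) * (1 - a)
  vPred <- a^2 * state@variance + q
  m <- mPred; v <- vPred
  if (!is.null(measurement)) {
    if (params@sigmaMeas <= 0)
      stop("sigmaMeas must be > 0 to assimilate a measurement")
    al <- params@alpha
    K <- vPred * al / (al^2 * vPred + params@sigmaMeas^2)
    m <- mPred + K * (measurement - al * mPred)
    v <- (1 - K * al) * vPred
  }
  new("KalmanState", mean = m, variance = v,
      inputBuffer = c(state@inputBuffer[-1], as.numeric(appliedLight)))
}
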