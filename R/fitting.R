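# Calibration of the deterministic expression model from characterisation
# data (several cell groups, each under a distinct binary light profile).
#
# For fixed (gamma, tau) the predicted fluorescence is linear in
# (p0, b0, k): F(t) = p0 * e^{-gamma t} + b0 * L0(t) + k * L1(t), with L0 and
# L1 the unit responses to basal production and to the delayed light input.
# The fit therefore profiles tau on a grid, optimises gamma in 1-D, and
# solves the inner problem by linear least squares - no multistart gradient
# search, no local minima in the linear block.

#' Fit the deterministic expression model to mean-fluorescence trajectories
#'
#' @param trajectories list of data.frames (one per group) with columns
#'   `time` (min, multiples of `dtMin`) and `fluor` (mean fluorescence).
#' @param lights list of [LightProfile-class], one per group.
#' @param tauGrid delay grid to profile over (min; multiples of `dtMin`).
#' @param dtMin integration grid (min).
#' @param gammaRange search interval for the removal rate (1/min).
#' @return list with `params` (a [GeneExpressionParams-class] in lumped
#'   fluorescence units, `alpha = 1`), `p0` per group, `residual` (sum of
#'   squared residuals), and `tauProfile` (residual per grid point).
#' @export
fitDeterministic <- function(trajectories, lights, tauGrid = seq(0, 60, by = 3),
                             dtMin = 3, gammaRange = c(1e-4, 0.2)) {
  stopifnot(length(trajectories) == length(lights), length(trajectories) >= 1)
  patterns <- vapply(lights, function(l) paste(as.integer(l@pulses),
                                               collapse = ""), "")
  if (length(unique(patterns)) < 2)
    warning("fewer than two distinct light profiles: k and gamma are ",
            "poorly identifiable")
  G <- length(trajectories)

  ssrFor <- function(gamma, tau, value = FALSE) {
    X <- NULL; y <- NULL
    for (g in seq_len(G)) {
      tt <- trajectories[[g]]$time
      horizon <- max(tt)
      pars0 <- GeneExpressionParams(k = 0, b0 = 1, gamma = gamma, tau = tau,
                                    alpha = 1, sigmaMeas = 1)
      pars1 <- GeneExpressionParams(k = 1, b0 = 0, gamma = gamma, tau = tau,
                                    alpha = 1, sigmaMeas = 1)
      L0 <- simulateDeterministic(pars0, lights[[g]], horizon, dtMin, p0 = 0)
      L1 <- simulateDeterministic(pars1, lights[[g]], horizon, dtMin, p0 = 0)
      i <- match(round(tt / dtMin), round(L0$time / dtMin))
      if (anyNA(i)) stop("trajectory times must lie on the dtMin grid")
      hom <- exp(-gamma * tt)
      Xg <- matrix(0, length(tt), G + 2)
      Xg[, g] <- hom                      # per-group initial condition
      Xg[, G + 1] <- L0$protein[i]        # basal production response
      Xg[, G + 2] <- L1$protein[i]        # light-induced response
      X <- rbind(X, Xg)
      y <- c(y, trajectories[[g]]$fluor)
    }
    fit <- stats::lm.fit(X, y)
    ssr <- sum(fit$residuals^2)
    if (!value) return(ssr)
    list(ssr = ssr, coef = fit$coefficients)
  }

  best <- NULL
  tauProfile <- data.frame(tau = tauGrid, ssr = NA_real_, gamma = NA_real_)
  for (ti in seq_along(tauGrid)) {
    opt <- stats::optimize(function(g) ssrFor(g, tauGrid[ti]),
                           interval = gammaRange, tol = 1e-7)
    tauProfile$ssr[ti] <- opt$objective
    tauProfile$gamma[ti] <- opt$minimum
    if (is.null(best) || opt$objective < best$ssr)
      best <- list(tau = tauGrid[ti], gamma = opt$minimum, ssr = opt$objective)
  }
  final <- ssrFor(best$gamma, best$tau, value = TRUE)
  cf <- final$coef
  cf[is.na(cf)] <- 0
  list(params = GeneExpressionParams(k = max(cf[G + 2], 0),
                                     b0 = max(cf[G + 1], 0),
                                     gamma = best$gamma, tau = best$tau,
                                     alpha = 1, sigmaMeas = 1),
       p0 = cf[seq_len(G)], residual = final$ssr, tauProfile = tauProfile)
}
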