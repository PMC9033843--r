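# Light-driven gene expression models.
#
# Both models share one structure: protein is produced at rate
# b0 + k * u(t - tau) and removed at rate gamma * P, where u is the binary
# light activation of each measurement interval and tau a deterministic
# delay (fluorophore maturation). The deterministic model is the "average
# cell"; the stochastic birth-death model is the "single cell".

# internal: delayed activation u(t - tau) for a LightProfile, vectorised over t.
# u = 0 before the first interval takes effect and after the profile ends.
delayedActivation <- function(t, light, tau) {
  u <- lightActivation(light)
  ts <- t - tau
  idx <- floor(ts / light@stepMin) + 1
  out <- numeric(length(t))
  ok <- ts >= 0 & idx >= 1 & idx <= length(u)
  out[ok] <- u[idx[ok]]
  out
}

#' Simulate the deterministic ("average cell") expression model
#'
#' Integrates `dP/dt = b0 + k * u(t - tau) - gamma * P` exactly on a grid of
#' `dtMin`-minute pieces (the input is piecewise constant, so each piece has
#' a closed-form solution; no ODE solver error).
#'
#' @param params a [GeneExpressionParams-class].
#' @param light a [LightProfile-class].
#' @param horizonMin total simulated time (min).
#' @param dtMin output/integration grid (min); must divide `stepMin` and
#'   `tau` must be a multiple of it so interval edges fall on the grid.
#' @param p0 initial protein level (>= 0).
#' @return data.frame with columns `time` (min) and `protein`.
#' @export
simulateDeterministic <- function(params, light, horizonMin, dtMin = 1, p0 = 0) {
  if (p0 < 0) stop("p0 must be >= 0")
  if (abs(light@stepMin / dtMin - round(light@stepMin / dtMin)) > 1e-9)
    stop("dtMin must divide the light profile step")
  if (abs(params@tau / dtMin - round(params@tau / dtMin)) > 1e-9)
    stop("tau must be a multiple of dtMin")
  nsteps <- ceiling(horizonMin / dtMin)
  tgrid <- seq(0, by = dtMin, length.out = nsteps + 1)
  u <- delayedActivation(tgrid[-length(tgrid)], light, params@tau)
  decay <- exp(-params@gamma * dtMin)
  P <- numeric(nsteps + 1)
  P[1] <- p0
  gain <- (1 - decay) / params@gamma
  for (i in seq_len(nsteps))
    P[i + 1] <- P[i] * decay + (params@b0 + params@k * u[i]) * gain
  data.frame(time = tgrid, protein = P)
}

#' Simulate the stochastic ("single cell") model by the exact SSA
#'
#' Event-driven Gillespie simulation of the birth--death process with birth
#' propensity `b0 + k * u(t - tau)` (piecewise constant) and death propensity
#' `gamma * n`. Propensity changes at interval boundaries are handled by
#' advancing to the boundary and redrawing.
#'
#' @param params a [GeneExpressionParams-class].
#' @param light a [LightProfile-class].
#' @param horizonMin total simulated time (min).
#' @param n0 integer initial copy number (>= 0).
#' @return data.frame of the jump trajectory: columns `time`, `count`;
#'   first row is `(0, n0)`, later rows are post-jump states.
#' @export
simulateSSA <- function(params, light, horizonMin, n0 = 0) {
  if (n0 < 0 || n0 != round(n0)) stop("n0 must be a non-negative integer")
  step <- light@stepMin
  bounds <- unique(sort(c(seq(0, horizonMin, by = step) + params@tau %% step,
                          seq(0, horizonMin, by = step), horizonMin)))
  bounds <- bounds[bounds > 0 & bounds <= horizonMin]
  times <- numeric(64); counts <- numeric(64); m <- 1L
  times[1] <- 0; counts[1] <- n0
  t <- 0; n <- n0; bi <- 1L
  repeat {
    nextBound <- if (bi <= length(bounds)) bounds[bi] else horizonMin
    b <- params@b0 + params@k * delayedActivation(t, light, params@tau)
    a <- b + params@gamma * n
    if (a <= 0) { t <- nextBound } else {
      dt <- stats::rexp(1, a)
      if (t + dt >= nextBound) { t <- nextBound } else {
        t <- t + dt
        n <- if (stats::runif(1) < b / a) n + 1 else n - 1
        m <- m + 1L
        if (m > length(times)) {
          times <- c(times, numeric(length(times)))
          counts <- c(counts, numeric(length(counts)))
        }
        times[m] <- t; counts[m] <- n
        next
      }
    }
    if (t >= horizonMin) break
    if (bi <= length(bounds) && t >= bounds[bi]) bi <- bi + 1L
  }
  data.frame(time = times[seq_len(m)], count = counts[seq_len(m)])
}

#' Value of a jump trajectory at given times
#'
#' @param traj data.frame from [simulateSSA()].
#' @param times numeric vector of query times.
#' @return counts at the requested times (right-continuous step function).
#' @export
ssaStateAt <- function(traj, times) {
  idx <- findInterval(times, traj$time)
  idx[idx < 1L] <- 1L
  traj$count[idx]
}

#' Exact one-interval transition of the stochastic model, vectorised
#'
#' For the immigration--death process with constant birth rate over an
#' interval, the end-of-interval copy number given the start is exactly
#' `Binomial(n, exp(-gamma*dt)) + Poisson(b/gamma * (1 - exp(-gamma*dt)))`
#' (surviving molecules plus newly produced-and-surviving ones). Used to
#' advance whole populations one measurement interval at a time without an
#' event loop; distributionally identical to [simulateSSA()].
#'
#' @param n integer vector of copy numbers.
#' @param u activation level(s) in `[0, 1]` for the interval (recycled).
#' @param dtMin interval length (min).
#' @param params a [GeneExpressionParams-class].
#' @return integer vector of end-of-interval copy numbers.
#' @export
ssaIntervalStep <- function(n, u, dtMin, params) {
  s <- exp(-params@gamma * dtMin)
  b <- params@b0 + params@k * u
  surv <- stats::rbinom(length(n), n, s)
  born <- stats::rpois(length(n), b / params@gamma * (1 - s))
  surv + born
}
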