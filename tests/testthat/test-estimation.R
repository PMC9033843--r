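# Kalman filter, FSP propagation/update, model fitting.

test_that("Kalman limits: gain -> 1 as noise vanishes; predict-only = model", {
  p <- GeneExpressionParams(k = 1, b0 = 0.1, gamma = 0.05, tau = 12,
                            alpha = 2, sigmaMeas = 1e-9)
  ks <- KalmanState(5, 4, p, stepMin = 6)
  out <- kalmanStep(ks, TRUE, measurement = 14, params = p, stepMin = 6, q = 0)
  expect_equal(out@mean, 14 / p@alpha, tolerance = 1e-6)

  p2 <- p; p2@sigmaMeas <- 5
  ks2 <- KalmanState(5, 0, p2, stepMin = 6)
  ks2@inputBuffer <- c(1, 0)
  pred <- kalmanStep(ks2, FALSE, measurement = NULL, params = p2,
                     stepMin = 6, q = 0)
  a <- exp(-p2@gamma * 6)
  expect_equal(pred@mean, a * 5 + (p2@b0 + p2@k) * (1 - a) / p2@gamma,
               tolerance = 1e-12)
  expect_error(kalmanStep(ks2, FALSE, measurement = 3,
                          params = { pp <- p2; pp@sigmaMeas <- 0; pp },
                          stepMin = 6), "sigmaMeas")
})

test_that("Kalman variance never increases across a measurement update", {
  p <- GeneExpressionParams(k = 0.5, b0 = 0.05, gamma = 0.03, tau = 6,
                            alpha = 3, sigmaMeas = 8)
  ks <- KalmanState(2, 1, p, stepMin = 6)
  set.seed(4)
  for (i in 1:15) {
    u <- ks@inputBuffer[1]
    a <- exp(-p@gamma * 6)
    vPred <- a^2 * ks@variance +
      a * (1 - a) * max(ks@mean, 0) +
      (p@b0 + p@k * u) / p@gamma * (1 - a)
    ks <- kalmanStep(ks, runif(1) < 0.5, measurement = rnorm(1, 3 * ks@mean, 8),
                     params = p, stepMin = 6)
    expect_lte(ks@variance, vPred + 1e-12)
  }
})

test_that("Kalman posterior means match a dense-grid Bayes filter", {
  p <- GeneExpressionParams(k = 1, b0 = 0.1, gamma = 0.05, tau = 12,
                            alpha = 2, sigmaMeas = 4)
  step <- 6
  a <- exp(-p@gamma * step)
  set.seed(6)
  lights <- runif(20) < 0.5
  # truth and measurements from the linear-Gaussian system itself
  qOf <- function(m, u) a * (1 - a) * max(m, 0) +
    (p@b0 + p@k * u) / p@gamma * (1 - a)
  grid <- seq(-20, 120, length.out = 2500)
  gprior <- dnorm(grid, 0, 0.3); gprior <- gprior / sum(gprior)
  ks <- KalmanState(0, 0.09, p, stepMin = step)
  buf <- c(0, 0)
  truth <- 0
  for (t in seq_along(lights)) {
    u <- buf[1]
    q <- qOf(ks@mean, u)
    truth <- a * truth + (p@b0 + p@k * u) / p@gamma * (1 - a) +
      rnorm(1, 0, sqrt(q))
    y <- p@alpha * truth + rnorm(1, 0, p@sigmaMeas)
    # oracle: exact Chapman-Kolmogorov on the grid, then Bayes
    trans <- outer(grid, grid, function(xn, xo)
      dnorm(xn, a * xo + (p@b0 + p@k * u) / p@gamma * (1 - a), sqrt(q)))
    gprior <- as.numeric(trans %*% gprior)
    gprior <- gprior * dnorm(y, p@alpha * grid, p@sigmaMeas)
    gprior <- gprior / sum(gprior)
    ks <- kalmanStep(ks, lights[t], measurement = y, params = p,
                     stepMin = step, q = q)
    buf <- c(buf[-1], as.numeric(lights[t]))
    gridMean <- sum(grid * gprior)
    expect_lt(abs(ks@mean - gridMean) / max(abs(gridMean), 1), 0.01)
  }
})

test_that("FSP conserves probability and reaches the Poisson stationary law", {
  p <- GeneExpressionParams(k = 1.2, b0 = 0.1, gamma = 0.1, tau = 6,
                            alpha = 1, sigmaMeas = 1)
  N <- as.integer(ceiling(8 * (p@b0 + p@k) / p@gamma))
  fs <- FspState(p, N = N, stepMin = 6)
  expect_identical(fspPropagate(fs, TRUE, 0, p), fs)      # dt = 0 no-op
  kern <- fspKernels(p, N, 6)
  for (i in 1:200) {
    fs <- fspPropagate(fs, TRUE, 6, p, kern)
    expect_lt(abs(sum(fs@p) + fs@leaked - 1), 1e-9)
  }
  mu <- (p@b0 + p@k) / p@gamma
  theo <- dpois(0:N, mu)
  expect_lt(0.5 * (sum(abs(fs@p - theo)) + (1 - sum(theo)) + fs@leaked), 1e-3)

  # all rates ~ zero: distribution and leak unchanged
  p0 <- GeneExpressionParams(k = 0, b0 = 0, gamma = 1e-300, tau = 0,
                             alpha = 1, sigmaMeas = 1)
  fs0 <- FspState(p0, N = 10, stepMin = 6)
  fs0@p <- dpois(0:10, 2); fs0@p <- fs0@p / sum(fs0@p)
  out <- fspPropagate(fs0, FALSE, 6, p0)
  expect_equal(out@p, fs0@p, tolerance = 1e-12)
  expect_equal(out@leaked, fs0@leaked, tolerance = 1e-12)
})

test_that("FSP measurement update is exact Bayes; leak resets", {
  p <- GeneExpressionParams(k = 1, b0 = 0.1, gamma = 0.1, tau = 6,
                            alpha = 10, sigmaMeas = 3)
  fs <- FspState(p, N = 60, stepMin = 6)
  fs@p <- dpois(0:60, 8); fs@leaked <- 1 - sum(fs@p)

  # flat likelihood keeps the prior (up to renormalisation)
  pFlat <- p; pFlat@sigmaMeas <- 1e9
  out <- fspUpdate(fs, 50, pFlat)
  expect_equal(out@p, fs@p / sum(fs@p), tolerance = 1e-9)
  expect_identical(out@leaked, 0)

  # near-delta likelihood concentrates at the measured count
  pSharp <- p; pSharp@sigmaMeas <- 0.01
  out2 <- fspUpdate(fs, 10 * 12, pSharp)
  expect_gt(out2@p[13], 0.999)

  # incompatible measurement falls back to the prior with a warning
  expect_warning(out3 <- fspUpdate(fs, 1e6, p), "incompatible")
  expect_equal(out3@p, fs@p / sum(fs@p), tolerance = 1e-12)
})

test_that("propagate+update chain equals an exhaustive Bayes recursion", {
  p <- GeneExpressionParams(k = 0.9, b0 = 0.2, gamma = 0.08, tau = 12,
                            alpha = 5, sigmaMeas = 6)
  N <- 50L
  kern <- fspKernels(p, N, 6)
  fs <- FspState(p, N = N, stepMin = 6)
  set.seed(10)
  lights <- runif(10) < 0.5
  ys <- rnorm(10, 40, 15)
  # clean-room recursion: uniformization kernels + explicit Bayes weights
  K0 <- uniformizationKernel(N, p@b0, p@gamma, 6)
  K1 <- uniformizationKernel(N, p@b0 + p@k, p@gamma, 6)
  aug <- c(fs@p, 0)
  buf <- c(0, 0)
  for (t in 1:10) {
    K <- if (buf[1] >= 0.5) K1 else K0
    aug <- as.numeric(K %*% aug)
    w <- c(dnorm(ys[t], p@alpha * (0:N), p@sigmaMeas), 0)
    aug <- aug * w
    aug <- aug / sum(aug)
    fs <- fspPropagate(fs, lights[t], 6, p, kern)
    fs <- fspUpdate(fs, ys[t], p)
    buf <- c(buf[-1], as.numeric(lights[t]))
    expect_lt(max(abs(fs@p - aug[1:(N + 1)])), 1e-10)
  }
})

test_that("FSP posterior mean approaches the Kalman mean at high counts", {
  # stationary mean > 200 molecules
  p <- GeneExpressionParams(k = 2.5, b0 = 0.1, gamma = 0.01, tau = 6,
                            alpha = 1, sigmaMeas = 10)
  mu <- (p@b0 + p@k) / p@gamma
  N <- as.integer(mu + 8 * sqrt(mu))
  kern <- fspKernels(p, N, 6)
  fs <- FspState(p, N = N, p = dpois(0:N, mu * 0.8), stepMin = 6)
  fs@leaked <- 1 - sum(fs@p); fs <- fspUpdate(fs, mu * 0.8, p)  # normalise
  ks <- KalmanState(fspMean(fs), mu * 0.8, p, stepMin = 6)
  set.seed(12)
  for (t in 1:8) {
    y <- rnorm(1, mu * 0.9, p@sigmaMeas)
    fs <- fspUpdate(fspPropagate(fs, TRUE, 6, p, kern), y, p)
    ks <- kalmanStep(ks, TRUE, measurement = y, params = p, stepMin = 6)
    expect_lt(abs(fspMean(fs) - ks@mean) / ks@mean, 0.05)
  }
})

test_that("division re-initialisation is binomial thinning", {
  p <- GeneExpressionParams(k = 1, b0 = 0, gamma = 0.1, tau = 6,
                            alpha = 1, sigmaMeas = 1)
  fs <- FspState(p, N = 30, stepMin = 6)
  fs@p <- rep(0, 31); fs@p[21] <- 1                 # all mass at n = 20
  d <- fspDivide(fs, q = 0.5)
  expect_equal(d@p[1:21], dbinom(0:20, 20, 0.5), tolerance = 1e-12)
})

test_that("fit recovers parameters; flags unidentifiable designs", {
  truth <- GeneExpressionParams(k = 20, b0 = 1, gamma = 0.01, tau = 36,
                                alpha = 1, sigmaMeas = 1)
  profiles <- characterizationProfiles(60)
  traj <- lapply(profiles, function(lp) {
    tr <- simulateDeterministic(truth, lp, 360, dtMin = 3)
    keep <- tr$time %% 6 == 0
    data.frame(time = tr$time[keep], fluor = tr$protein[keep])
  })
  fit <- fitDeterministic(traj, profiles, tauGrid = seq(0, 60, 3), dtMin = 3)
  expect_equal(fit$params@tau, 36)
  expect_lt(abs(fit$params@k - 20) / 20, 0.01)
  expect_lt(abs(fit$params@gamma - 0.01) / 0.01, 0.01)

  expect_warning(
    fitDeterministic(traj[1], profiles[1], tauGrid = c(30, 36), dtMin = 3),
    "identifiab")
})
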