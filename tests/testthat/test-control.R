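# Exposure controller, MPC candidate enumeration/selection, open-loop
# precomputation, performance metric.

test_that("exposure controller applies the deadband/step/clamp rules", {
  prm <- ExposureControllerParams(target = 3000, deadband = 200, step = 50,
                                  eMin = 10, eMax = 400)
  expect_equal(exposureStep(2500, 100, prm), 150)     # below band: +step
  expect_equal(exposureStep(3000, 100, prm), 100)     # in band: unchanged
  expect_equal(exposureStep(3150, 100, prm), 100)     # still inside deadband
  expect_equal(exposureStep(3500, 100, prm), 50)      # above band: -step
  expect_equal(exposureStep(2000, 400, prm), 400)     # clamped at eMax
  expect_equal(exposureStep(9000, 40, prm), 10)       # clamped at eMin
})

test_that("exposure controller converges into the deadband on a monotone plant", {
  prm <- ExposureControllerParams(target = 1000, deadband = 50, step = 20,
                                  eMin = 5, eMax = 500)
  gain <- 8                       # fluorescence per ms of exposure
  e <- 30
  for (i in 1:40) e <- exposureStep(gain * e, e, prm)
  expect_lte(abs(gain * e - 1000), prm@deadband + prm@step * gain)
})

test_that("candidate set enumerates 2^H profiles, off-first order", {
  m <- candidateProfiles(4)
  expect_identical(dim(m), c(16L, 4L))
  expect_false(any(m[1, ]))
  expect_true(all(m[16, ]))
  expect_identical(anyDuplicated(apply(m, 1, paste, collapse = "")), 0L)
  # lexicographic: first differing step is off in the earlier row
  expect_identical(m[2, ], c(FALSE, FALSE, FALSE, TRUE))
})

test_that("deterministic MPC: ties break to all-off when dark tracking works", {
  p <- GeneExpressionParams(k = 1, b0 = 0.2, gamma = 0.05, tau = 12,
                            alpha = 10, sigmaMeas = 5)
  # target = the trajectory the dark system follows from its stationary point
  mu0 <- p@b0 / p@gamma
  task <- ControlTask(rep(p@alpha * mu0, 20), horizonSteps = 4L, cost = "mse")
  ks <- KalmanState(mu0, 0, p, stepMin = 6)
  sel <- mpcSelectDeterministic(ks, task, p, currentStep = 0L)
  expect_false(sel$apply)
  expect_false(any(sel$profile))
})

test_that("deterministic MPC equals a clean-room exhaustive search", {
  set.seed(19)
  for (rep in 1:5) {
    p <- GeneExpressionParams(k = runif(1, 0.5, 2), b0 = runif(1, 0, 0.3),
                              gamma = runif(1, 0.02, 0.1),
                              tau = sample(c(6, 12, 18), 1),
                              alpha = 10, sigmaMeas = 5)
    H <- sample(3:5, 1)
    task <- ControlTask(runif(40, 0, 200), horizonSteps = H, cost = "mse")
    ks <- KalmanState(runif(1, 0, 20), 1, p, stepMin = 6)
    ks@inputBuffer <- as.numeric(runif(length(ks@inputBuffer)) < 0.5)
    t0 <- sample(0:5, 1)
    sel <- mpcSelectDeterministic(ks, task, p, currentStep = t0)

    # oracle: independent enumeration and propagation
    D <- length(ks@inputBuffer)
    a <- exp(-p@gamma * 6)
    prop <- function(m, u) a * m + (p@b0 + p@k * u) * (1 - a) / p@gamma
    m0 <- ks@mean
    for (d in seq_len(D)) m0 <- prop(m0, ks@inputBuffer[d])
    grid <- as.matrix(expand.grid(rep(list(c(0, 1)), H)))
    best <- NULL
    for (g in seq_len(nrow(grid))) {
      m <- m0; cost <- 0
      for (h in seq_len(H)) {
        m <- prop(m, grid[g, h])
        r <- task@targetProfile[min(t0 + D + h, length(task@targetProfile))]
        cost <- cost + (p@alpha * m - r)^2
      }
      key <- c(cost, sum(grid[g, ]), sum(grid[g, ] * 2^((H - 1):0)))
      if (is.null(best) || cost < best$cost - 1e-12 ||
          (abs(cost - best$cost) <= 1e-12 && (key[2] < best$key[2] ||
            (key[2] == best$key[2] && key[3] < best$key[3])))) {
        best <- list(cost = cost, profile = grid[g, ] > 0, key = key)
      }
    }
    expect_equal(sel$cost, best$cost, tolerance = 1e-9, ignore_attr = TRUE)
    expect_identical(unname(sel$profile), unname(best$profile))
  }
})

test_that("expected absolute deviation matches direct summation", {
  p <- dpois(0:30, 6); p <- p / sum(p)
  direct <- sum(p * abs(10 * (0:30) - 47))
  expect_equal(expectedAbsDeviation(p, 10, 47), direct, tolerance = 1e-12)
})

test_that("single-cell MPC: zero cost and all-off for a degenerate on-target state", {
  p <- GeneExpressionParams(k = 0, b0 = 0, gamma = 1e-9, tau = 6,
                            alpha = 10, sigmaMeas = 5)
  N <- 60L
  fs <- FspState(p, N = N, stepMin = 6)
  fs@p <- rep(0, N + 1); fs@p[6] <- 1        # exactly n = 5, frozen dynamics
  task <- ControlTask(rep(50, 20), horizonSteps = 3L, cost = "ead")
  sel <- mpcSelectSingleCell(fs, task, p, currentStep = 0L)
  expect_lt(sel$cost, 1e-3)          # matrix-exponential roundoff only
  expect_false(any(sel$profile))
})

test_that("single-cell MPC equals a clean-room exhaustive search", {
  set.seed(29)
  for (rep in 1:5) {
    p <- GeneExpressionParams(k = runif(1, 0.5, 1.5), b0 = runif(1, 0, 0.2),
                              gamma = runif(1, 0.05, 0.15), tau = 12,
                              alpha = 10, sigmaMeas = 5)
    N <- 60L
    H <- 3L
    task <- ControlTask(runif(30, 0, 120), horizonSteps = H, cost = "ead")
    fs <- FspState(p, N = N, stepMin = 6)
    fs@p <- dpois(0:N, runif(1, 1, 8)); fs@leaked <- 1 - sum(fs@p)
    fs@inputBuffer <- as.numeric(runif(2) < 0.5)
    kern <- fspKernels(p, N, 6)
    t0 <- sample(0:3, 1)
    sel <- mpcSelectSingleCell(fs, task, p, kern, currentStep = t0)

    K0 <- uniformizationKernel(N, p@b0, p@gamma, 6)
    K1 <- uniformizationKernel(N, p@b0 + p@k, p@gamma, 6)
    D <- length(fs@inputBuffer)
    v0 <- c(fs@p, fs@leaked)
    for (d in seq_len(D))
      v0 <- as.numeric((if (fs@inputBuffer[d] >= 0.5) K1 else K0) %*% v0)
    grid <- as.matrix(expand.grid(rep(list(c(0, 1)), H)))[, H:1, drop = FALSE]
    costs <- apply(grid, 1, function(g) {
      v <- v0; cost <- 0
      for (h in seq_len(H)) {
        v <- as.numeric((if (g[h] > 0) K1 else K0) %*% v)
        r <- task@targetProfile[min(t0 + D + h, length(task@targetProfile))]
        cost <- cost + sum(v[1:(N + 1)] * abs(p@alpha * (0:N) - r))
      }
      cost
    })
    o <- order(costs, rowSums(grid), seq_len(nrow(grid)))
    expect_equal(sel$cost, costs[o[1]], tolerance = 1e-8, ignore_attr = TRUE)
    expect_identical(unname(sel$profile), unname(grid[o[1], ] > 0))
  }
})

test_that("open-loop planner returns all-off for a dark target; is self-consistent", {
  p <- GeneExpressionParams(k = 1, b0 = 0, gamma = 0.05, tau = 12,
                            alpha = 10, sigmaMeas = 5)
  task0 <- ControlTask(rep(0, 30), horizonSteps = 4L, cost = "mse")
  prof <- precomputeOpenLoop(p, task0, 12)
  expect_false(any(prof@pulses))

  task <- ControlTask(rep(80, 30), horizonSteps = 4L, cost = "mse")
  prof2 <- precomputeOpenLoop(p, task, 12)
  tr <- simulateDeterministic(p, prof2, 72, dtMin = 6, p0 = 0)
  # replanning from the realised model state chooses the same next input
  ks <- KalmanState(0, 0, p, stepMin = 6)
  for (t in 1:12) {
    sel <- mpcSelectDeterministic(ks, task, p, currentStep = t - 1L)
    expect_identical(sel$apply, prof2@pulses[t])
    ks <- kalmanStep(ks, sel$apply, NULL, p, stepMin = 6, q = 0)
    expect_equal(ks@mean, tr$protein[tr$time == t * 6], tolerance = 1e-9)
  }
})

test_that("population MPC regulates a deterministic plant to a reachable target", {
  # binary 6-min pulses quantise the reachable set: the steady limit cycle
  # has amplitude ~ alpha*k*(1-a)/gamma, so the noise scale is set above it
  p <- GeneExpressionParams(k = 1, b0 = 0.05, gamma = 0.04, tau = 12,
                            alpha = 10, sigmaMeas = 30)
  target <- 0.6 * p@alpha * (p@b0 + p@k) / p@gamma      # reachable
  task <- ControlTask(rep(target, 60), horizonSteps = 4L, cost = "mse")
  ks <- KalmanState(0, 0, p, stepMin = 6)
  plant <- 0; buf <- c(0, 0)
  a <- exp(-p@gamma * 6)
  devs <- numeric(40)
  for (t in 1:40) {
    sel <- mpcSelectDeterministic(ks, task, p, currentStep = t - 1L)
    plant <- a * plant + (p@b0 + p@k * buf[1]) * (1 - a) / p@gamma
    buf <- c(buf[-1], as.numeric(sel$apply))
    y <- p@alpha * plant
    ks <- kalmanStep(ks, sel$apply, measurement = y, params = p, stepMin = 6)
    devs[t] <- abs(y - target)
  }
  expect_true(all(devs[15:40] <= 2 * p@sigmaMeas))
})

test_that("control performance metric is the time-averaged deviation", {
  expect_equal(controlPerformance(c(5, 5, 5), 5), 0)
  expect_equal(controlPerformance(c(4, 6), 5), 1)
  expect_equal(controlPerformance(c(4, 6), 5, type = "squared"), 1)
})

test_that("round-robin group assignment balances groups", {
  g <- assignGroups(c(11L, 3L, 7L, 20L, 5L, 9L), 3L)
  expect_identical(as.integer(sort(table(g))), c(2L, 2L, 2L))
  # increasing-id order: 3,5,7,9,11,20 -> groups 1,2,3,1,2,3
  expect_identical(g[order(c(11, 3, 7, 20, 5, 9))], rep(1:3, 2))
})
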