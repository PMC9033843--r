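# Virtual microscope: rendering linearity, camera noise, DMD dosing with
# bleed-through, exposure handling.

test_that("empty scene renders at the background level", {
  img <- renderImage(initPopulation(0), "GFP", 100, quietParams())
  expect_equal(mean(img), 50)
  expect_error(renderImage(initPopulation(0), "GFP", 0, quietParams()),
               "exposureMs")
})

test_that("cell signal is linear in exposure and in copy number", {
  pop <- cellsAt(cbind(32, 32), r = 8, protein = 10)
  prm <- quietParams()
  inside <- truthLabels(pop, c(64L, 64L)) > 0
  sig <- vapply(c(20, 50, 100, 200, 400), function(e)
    mean(renderImage(pop, "GFP", e, prm)[inside]) - 50, 0)
  fit <- lm(sig ~ c(20, 50, 100, 200, 400))
  expect_gt(suppressWarnings(summary(fit)$r.squared), 0.99)
  expect_lt(abs(coef(fit)[1]), 1e-8)

  # with shot + read noise, doubling exposure doubles the mean signal
  noisy <- VirtualSampleParams(imageShape = c(64L, 64L), backgroundLevel = 50,
                               readNoiseSd = 2, shotNoise = TRUE)
  set.seed(8)
  m1 <- replicate(100, mean(renderImage(pop, "GFP", 50, noisy)[inside]) - 50)
  m2 <- replicate(100, mean(renderImage(pop, "GFP", 100, noisy)[inside]) - 50)
  se <- sqrt(var(m2) / 100 + 4 * var(m1) / 100)
  expect_lt(abs(mean(m2) - 2 * mean(m1)), 3 * se)

  sigN <- vapply(c(2, 5, 10, 20, 40), function(n) {
    p2 <- pop; p2$protein <- n
    mean(renderImage(p2, "GFP", 100, prm)[inside]) - 50
  }, 0)
  expect_gt(suppressWarnings(
    summary(lm(sigN ~ c(2, 5, 10, 20, 40)))$r.squared), 0.99)
})

test_that("dye signal decays exponentially at the configured rate", {
  rate <- log(2) / 170
  prm <- quietParams(dyeDecayRate = rate)
  pop <- cellsAt(cbind(32, 32), r = 8, dye = 20)
  inside <- truthLabels(pop, c(64L, 64L)) > 0
  times <- seq(0, 150, by = 30)
  sig <- vapply(times, function(t) {
    p2 <- pop
    for (i in seq_len(t / 30)) p2 <- stepPopulation(p2, 30, dyeDecayRate = rate,
                                                    jitterSd = 0)
    mean(renderImage(p2, "RFP", 100, prm)[inside]) - 50
  }, 0)
  fit <- lm(log(sig) ~ times)
  expect_lt(abs(-coef(fit)[2] - rate) / rate, 0.05)
})

test_that("DMD doses follow the blurred mask and conserve under full field", {
  shape <- c(64L, 64L)
  pop <- cellsAt(cbind(c(26, 40), c(32, 32)), r = 5)
  prm <- quietParams(shape, bleedPsfSigma = 2)
  empty <- StimulationMask(matrix(FALSE, 64, 64), 1000, 1)
  expect_true(all(dmdDose(pop, empty, prm) == 0))

  for (sg in c(0, 1, 3, 5)) {
    p2 <- quietParams(shape, bleedPsfSigma = sg)
    full <- StimulationMask(matrix(TRUE, 64, 64), 1000, 0.8)
    expect_equal(unname(dmdDose(pop, full, p2)), rep(800, 2), tolerance = 1e-6)
  }

  # mask over cell A only: neighbour B (within 3 sigma) gets 0 < dose < A's
  maskA <- truthLabels(pop[1, ], shape) > 0
  d <- dmdDose(pop, StimulationMask(maskA, 1000, 1), prm)
  expect_gt(d[["2"]], 0)
  expect_lt(d[["2"]], d[["1"]])

  # against a clean-room direct convolution oracle
  kern <- outer(-9:9, -9:9, function(i, j) exp(-(i^2 + j^2) / (2 * 2^2)))
  kern <- kern / sum(kern)
  field <- matrix(0, 64, 64)
  for (i in 1:64) for (j in 1:64) {
    ii <- i + (-9:9); jj <- j + (-9:9)
    ok <- ii >= 1 & ii <= 64
    okj <- jj >= 1 & jj <= 64
    field[i, j] <- sum(kern[ok, okj] * maskA[ii[ok], jj[okj]])
  }
  oracle <- vapply(1:2, function(k) {
    m <- truthLabels(pop[k, ], shape) > 0
    mean(field[m]) * 1000
  }, 0)
  expect_equal(unname(d), oracle, tolerance = 0.03)

  bad <- StimulationMask(matrix(TRUE, 32, 32), 1000, 1)
  expect_error(dmdDose(pop, bad, prm), "shape")
})

test_that("exposure is per channel and per position, clamped with a warning", {
  pops <- list(pos1 = cellsAt(cbind(32, 32), r = 8, protein = 10),
               pos2 = cellsAt(cbind(32, 32), r = 8, protein = 10))
  scope <- VirtualMicroscope(quietParams(), pops, exposureBounds = c(1, 500))
  setExposure(scope, "GFP", 120, position = "pos1")
  expect_equal(getExposure(scope, "GFP", "pos1"), 120)
  expect_equal(getExposure(scope, "GFP", "pos2"), 100)   # untouched
  expect_equal(getExposure(scope, "RFP", "pos1"), 100)   # other channel
  img <- snapImage(scope, "GFP", "pos1")
  inside <- truthLabels(pops$pos1, c(64L, 64L)) > 0
  expect_equal(mean(img[inside]), 50 + 1 * 120 * 10, tolerance = 1e-9)

  got <- setExposure(scope, "GFP", 9999, position = "pos1")
  expect_equal(got, 500)
  warns <- logRecords(scope@env$logger, severity = "warning")
  expect_length(warns, 1)
  expect_match(warns[[1]]$message, "clamped")
})

test_that("stimulation appends to the light history log", {
  pop <- cellsAt(cbind(32, 32), r = 6)
  scope <- VirtualMicroscope(quietParams(), list(pos1 = pop))
  mask <- StimulationMask(truthLabels(pop, c(64L, 64L)) > 0, 1000, 1,
                          frameIndex = 3L)
  d <- dmdStimulate(scope, mask)
  lh <- lightHistory(scope)
  expect_identical(nrow(lh), 1L)
  expect_equal(lh$dose, unname(d))
  expect_identical(lh$frame, 3L)
})
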