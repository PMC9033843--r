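# Segmentation, quantification, SNR, erosion.

test_that("blank image yields no labels; scenes segment with high IoU", {
  blank <- matrix(1000, 64, 64)
  expect_identical(nCells(segmentCells(blank)), 0L)

  set.seed(21)
  pop <- initPopulation(20, c(256L, 256L), meanRadius = 7)
  prm <- quietParams(c(256L, 256L))
  seg <- segmentCells(renderImage(pop, "brightfield", 20, prm))
  expect_identical(nCells(seg), 20L)
  truthLab <- truthLabels(pop, c(256L, 256L))
  for (i in seq_len(nrow(pop))) {
    tm <- truthLab == pop$id[i]
    lab <- seg@labelImage[round(pop$cx[i]) + 1, round(pop$cy[i]) + 1]
    expect_gt(lab, 0)
    sm <- seg@labelImage == lab
    expect_gte(sum(tm & sm) / sum(tm | sm), 0.8)
  }
})

test_that("single cell's label contains its ground-truth centroid", {
  pop <- cellsAt(cbind(30, 34), r = 7)
  seg <- segmentCells(renderImage(pop, "brightfield", 20, quietParams()))
  expect_identical(nCells(seg), 1L)
  expect_identical(seg@labelImage[31, 35], 1L)
})

test_that("quantification is the plain per-label mean, permutation-invariant", {
  lab <- matrix(0L, 8, 8)
  lab[1, 1:3] <- 1L
  lab[5, 5:6] <- 2L
  seg <- new("SegmentationResult", labelImage = lab,
             table = data.frame(label = 1:2, cx = c(0, 4), cy = c(1, 4.5),
                                area = c(3, 2)))
  img <- matrix(7, 8, 8)
  img[1, 1:3] <- c(10, 20, 30)
  q <- quantifyCells(seg, img)
  expect_equal(q$mean_fluor, c(20, 7))

  # uniform image: every cell reads the constant
  expect_equal(quantifyCells(seg, matrix(5, 8, 8))$mean_fluor, c(5, 5))

  # label permutation does not change per-cell values
  lab2 <- lab
  lab2[lab == 1L] <- 2L
  lab2[lab == 2L] <- 1L
  seg2 <- new("SegmentationResult", labelImage = lab2,
              table = data.frame(label = 1:2, cx = c(4, 0), cy = c(4.5, 1),
                                 area = c(2, 3)))
  q2 <- quantifyCells(seg2, img)
  expect_equal(sort(q$mean_fluor), sort(q2$mean_fluor))

  # empty label set is an empty result, not an error
  segE <- new("SegmentationResult", labelImage = matrix(0L, 4, 4),
              table = data.frame(label = integer(), cx = numeric(),
                                 cy = numeric(), area = numeric()))
  expect_identical(nrow(quantifyCells(segE, matrix(0, 4, 4))), 0L)
})

test_that("quantified fluorescence is proportional to molecule count", {
  set.seed(13)
  pop <- initPopulation(60, c(320L, 320L), meanRadius = 6)
  pop$protein <- sample(5:60, nrow(pop), replace = TRUE)
  prm <- VirtualSampleParams(imageShape = c(320L, 320L), backgroundLevel = 50,
                             readNoiseSd = 1, shotNoise = TRUE)
  seg <- segmentCells(renderImage(pop, "brightfield", 20, prm))
  q <- quantifyCells(seg, renderImage(pop, "GFP", 100, prm))
  # match each label to the nearest ground-truth cell
  truthIdx <- vapply(seq_len(nCells(seg)), function(i)
    which.min((pop$cx - seg@table$cx[i])^2 + (pop$cy - seg@table$cy[i])^2), 0L)
  fit <- lm(q$mean_fluor ~ pop$protein[truthIdx])
  expect_gt(summary(fit)$r.squared, 0.95)
})

test_that("SNR is cells-over-background and behaves under offsets", {
  lab <- matrix(0L, 16, 16)
  lab[4:6, 4:6] <- 1L
  seg <- new("SegmentationResult", labelImage = lab,
             table = data.frame(label = 1L, cx = 4, cy = 4, area = 9))
  img <- matrix(100, 16, 16)
  img[lab == 1L] <- 200
  expect_equal(snrRatio(seg, img, dilateRadius = 0), 2)
  expect_equal(snrRatio(seg, matrix(7, 16, 16), dilateRadius = 0), 1)
  # constant offset pulls SNR toward 1
  expect_lt(snrRatio(seg, img + 500, dilateRadius = 0), 2)
  expect_gt(snrRatio(seg, img + 500, dilateRadius = 0), 1)
  expect_error(snrRatio(seg, img - 100, dilateRadius = 0), "zero")
})

test_that("erosion matches disk geometry, falls back to the centroid pixel", {
  disk <- function(r, size = 31) {
    ij <- expand.grid(i = 1:size, j = 1:size)
    m <- matrix((ij$i - 16)^2 + (ij$j - 16)^2 <= r^2, size, size)
    m
  }
  m5 <- disk(5)
  expect_identical(erodeMask(m5, 0), m5)
  e2 <- erodeMask(m5, 2)
  # area within a 1-px ring of the analytic radius-3 disk
  expect_gte(sum(e2), pi * 2^2)
  expect_lte(sum(e2), pi * 4^2)
  # anti-extensive and monotone in radius
  expect_true(all(m5[e2]))
  e3 <- erodeMask(m5, 3)
  expect_true(all(e2[e3]))
  # over-erosion keeps exactly the centroid pixel
  big <- erodeMask(m5, 10)
  expect_identical(sum(big), 1L)
  expect_true(big[16, 16])
})
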