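# Targeting strategies: ring permanence, islet separation, eroded masks,
# endpoint classification, slow-growth phenotype of recombined lineages.

mkCells <- function(xy, ids = seq_len(nrow(xy))) {
  data.frame(track_id = ids, label = seq_len(nrow(xy)),
             cx = xy[, 1], cy = xy[, 2], area = 50)
}

test_that("ring targeting is permanent and annulus-exact", {
  ring <- RingRegion(c(50, 50), rInner = 10, rOuter = 20)
  reg <- TargetRegistry()
  inside <- mkCells(cbind(50 + 15, 50), ids = 1L)        # mid-annulus
  outside <- mkCells(cbind(50, 50), ids = 2L)            # centre hole
  reg <- ringUpdate(rbind(inside, outside), ring, reg, frame = 0L)
  expect_identical(targetedIds(reg), 1L)
  # cell 1 leaves the annulus: still targeted; cell 2 never enters: never is
  moved <- mkCells(cbind(c(50, 50), c(90, 50)), ids = 1:2)
  reg <- ringUpdate(moved, ring, reg, frame = 1L)
  expect_identical(targetedIds(reg), 1L)
  # boundary membership is inclusive
  onEdge <- mkCells(cbind(50 + 10, 50), ids = 3L)
  reg <- ringUpdate(onEdge, ring, reg, frame = 2L)
  expect_true(3L %in% targetedIds(reg))
})

test_that("islet selection maximises isolation and enforces d_min", {
  set.seed(33)
  xy <- cbind(runif(12, 0, 200), runif(12, 0, 200))
  cells <- mkCells(xy)
  reg <- TargetRegistry()
  reg <- isletSelect(cells, reg, dMin = 40, maxNew = 1L, frame = 0L)
  # first pick: the cell with the largest distance to its nearest neighbour
  nn <- vapply(1:12, function(i)
    min(sqrt((xy[-i, 1] - xy[i, 1])^2 + (xy[-i, 2] - xy[i, 2])^2)), 0)
  expect_identical(targetedIds(reg), cells$track_id[which.max(nn)])

  for (f in 1:8) reg <- isletSelect(cells, reg, dMin = 40, maxNew = 2L,
                                    frame = f)
  sel <- cells[cells$track_id %in% targetedIds(reg), ]
  d <- as.matrix(dist(sel[, c("cx", "cy")]))
  expect_true(all(d[upper.tri(d)] > 40))

  # candidates all within d_min of targets: nothing is added
  nTargets <- nrow(sel)
  clustered <- mkCells(cbind(sel$cx[1] + runif(5, -5, 5),
                             sel$cy[1] + runif(5, -5, 5)), ids = 100:104)
  reg2 <- isletSelect(rbind(sel[, names(clustered)], clustered), reg,
                      dMin = 40, maxNew = 3L, frame = 9L)
  expect_identical(nrow(reg2@targets), nTargets)
})

test_that("stimulation mask is the union of eroded masks of present targets", {
  shape <- c(96L, 96L)
  pop <- cellsAt(cbind(c(30, 48), c(48, 48)), r = 7)
  ts <- truthSegmentation(pop, shape)
  cells <- mkCells(cbind(pop$cx, pop$cy))
  cells$label <- match(pop$id, ts$ids)
  reg <- TargetRegistry()
  built0 <- buildStimulationMask(cells, ts$seg, reg, erosionRadius = 2)
  expect_false(any(built0$mask@pixels))              # no targets, empty mask

  reg@targets <- data.frame(track_id = 1L, first_target_frame = 0L)
  built <- buildStimulationMask(cells, ts$seg, reg, erosionRadius = 2)
  m <- built$mask@pixels
  eroded <- erodeMask(ts$seg@labelImage == cells$label[1], 2)
  expect_identical(m, eroded)
  # no mask pixel falls inside the non-targeted neighbour (pre-blur)
  other <- ts$seg@labelImage == cells$label[2]
  expect_identical(sum(m & other), 0L)
  expect_equal(built$mask@durationMs, 1000)

  # a targeted track absent this frame is skipped and reported
  reg@targets <- rbind(reg@targets,
                       data.frame(track_id = 99L, first_target_frame = 1L))
  built2 <- buildStimulationMask(cells, ts$seg, reg, erosionRadius = 2)
  expect_identical(built2$skipped, 99L)
  expect_identical(built2$mask@pixels, m)
})

test_that("endpoint classification splits phenotypes and lists outliers", {
  reg <- TargetRegistry()
  reg@targets <- data.frame(track_id = c(1L, 2L), first_target_frame = 0L)
  fluor <- c("1" = 3000, "2" = 60, "3" = 55, "4" = 2900)
  out <- classifyEndpoint(fluor, reg, threshold = 1500)
  expect_identical(out$targetedNotRecombined, 2L)
  expect_identical(out$recombinedNotTargeted, 4L)
  expect_equal(sort(out$targetedFluor), c(60, 3000))

  # perfect experiment: no outliers
  perfect <- classifyEndpoint(c("1" = 3000, "2" = 2800, "3" = 50),
                              { r <- TargetRegistry()
                                r@targets <- data.frame(
                                  track_id = 1:2, first_target_frame = 0L); r },
                              threshold = 1500)
  expect_length(perfect$targetedNotRecombined, 0)
  expect_length(perfect$recombinedNotTargeted, 0)

  # threshold above all values: nothing is called recombined
  none <- classifyEndpoint(fluor, reg, threshold = 5000)
  expect_identical(sum(none$table$recombined), 0L)
})

test_that("recombined lineages grow into smaller colonies", {
  rp <- RecombinationParams(growthFactorPost = 0.3, reporterDelay = 0)
  finalRatio <- vapply(1:20, function(s) {
    set.seed(100 + s)
    pop <- initPopulation(16, c(512L, 512L), meanRadius = 6,
                          growthRate = log(2) / 45)
    rec <- pop$id[seq(1, 16, by = 2)]
    pop$recombined <- pop$id %in% rec
    pop$rec_time <- ifelse(pop$recombined, 0, NA_real_)
    for (i in 1:40)
      pop <- stepPopulation(pop, 3, clockMin = (i - 1) * 3, recParams = rp,
                            areaDivide = 220, jitterSd = 0)
    founder <- function(id) {
      while (!is.na(pop$parent_id[match(id, pop$id)]))
        id <- pop$parent_id[match(id, pop$id)]
      id
    }
    fo <- vapply(pop$id, founder, 0L)
    sizes <- table(factor(fo %in% rec, levels = c(FALSE, TRUE)))
    unname(sizes["TRUE"] / sizes["FALSE"])
  }, 0)
  # one-sided: recombined colonies are smaller in essentially every run
  expect_lt(median(finalRatio), 1)
  expect_gt(mean(finalRatio < 1), 0.9)
  expect_lt(t.test(log(finalRatio), alternative = "less")$p.value, 0.01)
})
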