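# Ground-truth cell population.
#
# The simulated sample is a data.frame with one row per cell ("CellTruth"
# schema): id, parent_id, cx, cy (px, 0-based), a, b (ellipse semi-axes, px),
# theta (rad), protein (reporter molecules), dye (relative membrane-dye
# level), recombined, rec_time (min), growth_rate (1/min). Geometry grows
# exponentially, cells divide at an area threshold, molecules partition
# binomially, and recombined cells switch to slow growth after the reporter
# delay.

#' Create a synthetic cell population
#'
#' Cells are placed uniformly at random with rejection of strong overlaps
#' (monolayer-like), with log-normal size scatter around `meanRadius`.
#'
#' @param n number of cells.
#' @param imageShape (rows, cols) of the camera frame the cells live in.
#' @param meanRadius mean equivalent radius (px).
#' @param growthRate area growth rate (1/min).
#' @param protein0 initial reporter molecule count(s), recycled.
#' @param dye0 initial dye level(s), recycled.
#' @param margin keep centroids at least this many px from the border.
#' @return population data.frame (see package overview for the schema).
#' @export
initPopulation <- function(n, imageShape = c(256L, 256L), meanRadius = 7,
                           growthRate = log(2) / 90, protein0 = 0, dye0 = 0,
                           margin = 12) {
  if (n == 0L) return(emptyPopulation())
  cx <- numeric(n); cy <- numeric(n)
  placed <- 0L
  tries <- 0L
  while (placed < n && tries < 200L * n) {
    tries <- tries + 1L
    px <- stats::runif(1, margin, imageShape[1] - 1 - margin)
    py <- stats::runif(1, margin, imageShape[2] - 1 - margin)
    if (placed == 0L ||
        min((cx[seq_len(placed)] - px)^2 + (cy[seq_len(placed)] - py)^2) >
          (2.2 * meanRadius)^2) {
      placed <- placed + 1L
      cx[placed] <- px; cy[placed] <- py
    }
  }
  if (placed < n)
    warning("could only place ", placed, " of ", n, " cells without overlap")
  n <- placed
  size <- meanRadius * exp(stats::rnorm(n, 0, 0.1))
  ecc <- stats::runif(n, 1.1, 1.5)
  data.frame(
    id = seq_len(n), parent_id = NA_integer_,
    cx = cx[seq_len(n)], cy = cy[seq_len(n)],
    a = size * sqrt(ecc), b = size / sqrt(ecc),
    theta = stats::runif(n, 0, pi),
    protein = rep_len(protein0, n), dye = rep_len(dye0, n),
    recombined = FALSE, rec_time = NA_real_,
    growth_rate = growthRate)
}

emptyPopulation <- function() {
  data.frame(id = integer(), parent_id = integer(), cx = numeric(),
             cy = numeric(), a = numeric(), b = numeric(), theta = numeric(),
             protein = numeric(), dye = numeric(), recombined = logical(),
             rec_time = numeric(), growth_rate = numeric())
}

# internal: growth rate currently in effect per cell (slow-growth phenotype
# kicks in reporterDelay minutes after recombination)
effectiveGrowthRate <- function(pop, clockMin, recParams = NULL) {
  r <- pop$growth_rate
  if (!is.null(recParams) && any(pop$recombined)) {
    slow <- pop$recombined & !is.na(pop$rec_time) &
      clockMin >= pop$rec_time + recParams@reporterDelay
    r[slow] <- r[slow] * recParams@growthFactorPost
  }
  r
}

#' Advance the population by one time step
#'
#' Cell areas grow exponentially at each cell's growth rate (reduced after
#' recombination takes effect); cells whose area exceeds `areaDivide` split
#' into two halves along the major axis with molecules partitioned
#' binomially (or halved when `partition = "halve"`); centroids receive
#' Gaussian jitter followed by pairwise overlap relaxation; the dye level
#' decays exponentially.
#'
#' @param pop population data.frame.
#' @param dtMin step length (min).
#' @param clockMin experiment time at the start of the step (min).
#' @param dyeDecayRate exponential dye decay rate (1/min).
#' @param recParams optional [RecombinationParams-class] (slow-growth timing).
#' @param areaDivide division area threshold (px^2).
#' @param jitterSd centroid jitter SD (px per step).
#' @param partition `"binomial"` (stochastic counts) or `"halve"`.
#' @param imageShape optional (rows, cols) used to clamp centroids.
#' @return updated population data.frame.
#' @export
stepPopulation <- function(pop, dtMin, clockMin = 0, dyeDecayRate = 0,
                           recParams = NULL, areaDivide = 350,
                           jitterSd = 0.3, partition = "binomial",
                           imageShape = NULL) {
  if (dtMin <= 0) stop("dtMin must be > 0")
  if (nrow(pop) == 0L) return(pop)
  r <- effectiveGrowthRate(pop, clockMin, recParams)
  scale <- exp(r * dtMin / 2)            # area grows at rate r
  pop$a <- pop$a * scale
  pop$b <- pop$b * scale
  pop$dye <- pop$dye * exp(-dyeDecayRate * dtMin)

  area <- pi * pop$a * pop$b
  dividing <- which(area >= areaDivide)
  if (length(dividing)) {
    nextId <- max(pop$id) + 1L
    daughters <- pop[dividing, , drop = FALSE]
    for (j in seq_along(dividing)) {
      i <- dividing[j]
      off <- pop$a[i] / 2 * c(cos(pop$theta[i]), sin(pop$theta[i]))
      prot <- pop$protein[i]
      kept <- if (partition == "binomial" && prot == round(prot))
        stats::rbinom(1L, as.integer(prot), 0.5) else prot / 2
      daughters$id[j] <- nextId
      daughters$parent_id[j] <- pop$id[i]
      daughters$protein[j] <- prot - kept
      daughters$cx[j] <- pop$cx[i] - off[1]
      daughters$cy[j] <- pop$cy[i] - off[2]
      daughters$a[j] <- pop$a[i] / 2
      nextId <- nextId + 1L
      pop$protein[i] <- kept
      pop$cx[i] <- pop$cx[i] + off[1]
      pop$cy[i] <- pop$cy[i] + off[2]
      pop$a[i] <- pop$a[i] / 2
    }
    pop <- rbind(pop, daughters)
  }

  if (jitterSd > 0) {
    pop$cx <- pop$cx + stats::rnorm(nrow(pop), 0, jitterSd)
    pop$cy <- pop$cy + stats::rnorm(nrow(pop), 0, jitterSd)
  }
  if (!is.null(imageShape)) {
    pop$cx <- pmin(pmax(pop$cx, 2), imageShape[1] - 3)
    pop$cy <- pmin(pmax(pop$cy, 2), imageShape[2] - 3)
  }
  pop <- relaxOverlaps(pop)   # last, so the monolayer stays segmentable
  rownames(pop) <- NULL
  pop
}

# internal: push apart overlapping cells, few sweeps. The bounding circle
# (semi-major axis) is used so that even major-axis-aligned pairs - freshly
# divided daughters in particular - keep a thin gap, which keeps threshold
# segmentation of the monolayer well posed (no watershed splitting).
relaxOverlaps <- function(pop, iterations = 8L) {
  n <- nrow(pop)
  if (n < 2L) return(pop)
  rad <- pmax(pop$a, pop$b)
  for (it in seq_len(iterations)) {
    dx <- outer(pop$cx, pop$cx, "-")
    dy <- outer(pop$cy, pop$cy, "-")
    d <- sqrt(dx^2 + dy^2)
    minsep <- 1.02 * outer(rad, rad, "+")
    ov <- which(d < minsep & upper.tri(d), arr.ind = TRUE)
    if (nrow(ov) == 0L) break
    for (k in seq_len(nrow(ov))) {
      i <- ov[k, 1]; j <- ov[k, 2]
      dd <- max(d[i, j], 1e-6)
      push <- (minsep[i, j] - dd) / 2
      ux <- dx[j, i] / dd; uy <- dy[j, i] / dd   # from i toward j
      pop$cx[j] <- pop$cx[j] + ux * push; pop$cy[j] <- pop$cy[j] + uy * push
      pop$cx[i] <- pop$cx[i] - ux * push; pop$cy[i] <- pop$cy[i] - uy * push
    }
  }
  pop
}

#' Apply light-driven recombination to a population
#'
#' Cells receiving a dose at or above the threshold recombine with
#' probability `pRec` per stimulation; all other non-recombined cells
#' recombine spontaneously with probability `pSpont` this frame.
#' Recombination is irreversible; the reporter and the slow-growth phenotype
#' take effect `reporterDelay` minutes after the recombination time.
#'
#' @param pop population data.frame.
#' @param dose named numeric vector of light doses (ms * relative intensity)
#'   indexed by cell id, or a plain vector aligned with `pop` rows.
#' @param params a [RecombinationParams-class].
#' @param clockMin current experiment time (min).
#' @return updated population.
#' @export
applyRecombination <- function(pop, dose, params, clockMin) {
  if (nrow(pop) == 0L) return(pop)
  if (!is.null(names(dose))) {
    d <- rep(0, nrow(pop))
    idx <- match(names(dose), as.character(pop$id))
    d[idx[!is.na(idx)]] <- dose[!is.na(idx)]
    dose <- d
  }
  if (any(dose < 0)) stop("doses must be >= 0")
  stimulated <- !pop$recombined & dose >= params@doseThreshold
  hit <- stimulated & stats::runif(nrow(pop)) < params@pRec
  spont <- !pop$recombined & !stimulated &
    stats::runif(nrow(pop)) < params@pSpont
  newly <- hit | spont
  pop$recombined[newly] <- TRUE
  pop$rec_time[newly] <- clockMin
  pop
}

#' Recombination reporter level of each cell
#'
#' Zero until `reporterDelay` minutes after recombination, then a linear
#' ramp to `plateau` over `rampMin` minutes (simplest kinetics that makes
#' the endpoint phenotype bimodal).
#'
#' @param pop population data.frame.
#' @param clockMin current experiment time (min).
#' @param params a [RecombinationParams-class].
#' @param plateau plateau level (signal units per unit exposure gain).
#' @param rampMin ramp duration (min).
#' @return numeric vector of reporter levels.
#' @export
recReporterLevel <- function(pop, clockMin, params, plateau = 30, rampMin = 60) {
  lvl <- numeric(nrow(pop))
  on <- pop$recombined & !is.na(pop$rec_time) &
    clockMin >= pop$rec_time + params@reporterDelay
  if (any(on)) {
    dtm <- clockMin - (pop$rec_time[on] + params@reporterDelay)
    lvl[on] <- plateau * pmin(1, dtm / rampMin)
  }
  lvl
}

#' Dump the ground-truth state of a population as a data.frame row set
#'
#' One row per cell with frame/clock stamps; used for oracle-based tests and
#' written alongside the observed track tables.
#'
#' @param pop population data.frame.
#' @param frame frame index.
#' @param clockMin experiment time (min).
#' @return data.frame with id, lineage, centroid, protein, recombined.
#' @export
truthSnapshot <- function(pop, frame, clockMin) {
  if (nrow(pop) == 0L)
    return(data.frame(frame = integer(), clock_min = numeric(),
                      id = integer(), parent_id = integer(), cx = numeric(),
                      cy = numeric(), protein = numeric(), dye = numeric(),
                      recombined = logical()))
  data.frame(frame = frame, clock_min = clockMin, id = pop$id,
             parent_id = pop$parent_id, cx = pop$cx, cy = pop$cy,
             protein = pop$protein, dye = pop$dye,
             recombined = pop$recombined)
}
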