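# Runnable scenario presets.
#
# Four experiments exercise the full stack:
#  * adaptive_exposure  - two fields of view of dye-stained cells whose
#    signal decays; a reactive event adjusts the exposure each frame
#    (paired with a constant-exposure control run).
#  * characterization   - three cell groups under distinct binary light
#    profiles; the deterministic model is fitted with the delay profiled.
#  * mpc_comparison     - open-loop vs population-feedback vs single-cell
#    feedback control of expression on a matched stochastic population.
#  * recombination      - event-driven ring / islet light-targeting with
#    endpoint phenotype classification.

#' Round-robin group assignment for characterisation runs
#'
#' @param trackIds integer ids.
#' @param nGroups number of groups.
#' @return integer group per id (1..nGroups), assigned round-robin over the
#'   ids in increasing order.
#' @export
assignGroups <- function(trackIds, nGroups = 3L) {
  grp <- integer(length(trackIds))
  grp[order(trackIds)] <- (seq_along(trackIds) - 1L) %% nGroups + 1L
  grp
}

#' Run an experiment configuration
#'
#' Validates nothing further (pass an [ExperimentConfig-class] from
#' [validateConfig()]), dispatches to the scenario runner, and writes the
#' standard output set when `output_dir` is configured.
#'
#' @param config an [ExperimentConfig-class] (or raw config accepted by
#'   [validateConfig()]).
#' @return scenario-specific results list; always contains `trackTable`,
#'   `summary` and `logger`.
#' @export
runExperiment <- function(config) {
  if (!is(config, "ExperimentConfig")) config <- validateConfig(config)
  res <- switch(configValue(config, "scenario"),
    adaptive_exposure = runAdaptiveExposure(config),
    characterization = runCharacterization(config),
    mpc_comparison = runMpcComparison(config),
    recombination = runRecombination(config))
  outDir <- configValue(config, "output_dir")
  if (!is.na(outDir))
    writeOutputs(outDir, res$trackTable, config, summary = res$summary,
                 logger = res$logger, truth = res$truth)
  res
}

# ---------------------------------------------------------------------------
# adaptive exposure
# ---------------------------------------------------------------------------

# internal: population factory shared by adaptive/constant arms so both see
# the exact same sample
adaptiveExposurePopulations <- function(config) {
  v <- config@values
  streams <- rngStreams(v$seed)
  pops <- list()
  withStream(streams, "init", {
    for (pos in v$positions)
      pops[[pos]] <- initPopulation(v$sample$n_cells, v$sample$image_shape,
                                    meanRadius = v$sample$mean_radius,
                                    growthRate = v$sample$growth_rate_per_min,
                                    dye0 = v$sample$dye0)
  })
  pops
}

# internal: one arm of the adaptive-exposure experiment
runExposureArm <- function(config, pops, adaptive) {
  v <- config@values
  streams <- rngStreams(v$seed)
  logger <- ExperimentLogger()
  scope <- VirtualMicroscope(configSampleParams(config), pops,
                             logger = logger, streams = streams,
                             exposures = unlist(v$channels$exposures))
  ctrl <- ExposureControllerParams(target = v$control$target,
                                   deadband = v$control$deadband,
                                   step = v$control$step_ms,
                                   eMin = v$control$e_min,
                                   eMax = v$control$e_max)
  ch <- v$channels$fluorescence[1]
  state <- ExperimentState(positions = v$positions, channels = ch,
                           bfPeriodMin = v$periods$brightfield_min,
                           fluorEvery = as.integer(round(
                             v$periods$fluorescence_min /
                             v$periods$brightfield_min)),
                           logger = logger)
  state@analysisHooks <- list(makeSegmentationHook())
  state@userData$exposureLog <- NULL
  record <- Event(
    id = "record-fluorescence", recurrence = "always",
    trigger = function(s) length(s@channels) > 0 &&
                          s@frameIndex %% s@fluorEvery == 0L,
    effect = function(s, sc) {
      tt <- s@userData$trackTable
      rows <- tt[tt$frame == s@frameIndex, ]
      col <- paste0("fluor_", ch)
      for (pos in s@positions) {
        m <- mean(rows[[col]][rows$position == pos], na.rm = TRUE)
        s@userData$exposureLog <- rbind(s@userData$exposureLog,
          data.frame(frame = s@frameIndex, position = pos, measured = m,
                     exposure = getExposure(sc, ch, pos)))
        if (adaptive) {
          e2 <- exposureStep(m, getExposure(sc, ch, pos), ctrl)
          setExposure(sc, ch, e2, position = pos, frame = s@frameIndex)
        }
      }
      s
    })
  state <- registerEvent(state, record)
  for (f in seq_len(v$frames)) state <- evaluateFrame(state, scope, jitterSd = 0.2)
  # final-frame SNR per position on the dye channel
  finalSnr <- vapply(v$positions, function(pos) {
    if (is.null(state@segs[[pos]])) return(NA_real_)
    snrRatio(state@segs[[pos]],
             state@latestImages[[paste(pos, ch, sep = "/")]])
  }, 0)
  list(state = state, scope = scope, exposureLog = state@userData$exposureLog,
       trackTable = state@userData$trackTable, finalSnr = finalSnr,
       logger = logger)
}

#' Adaptive-exposure scenario: paired adaptive and constant runs
#'
#' Simulates dye-stained cells whose signal decays exponentially, in
#' parallel fields of view, twice from identical initial samples and seeds:
#' once with the constant-step exposure controller reacting after every
#' acquisition, once at constant exposure. Reports the measured mean
#' fluorescence and exposure per frame and position, and the final-frame
#' SNR of both arms.
#'
#' @param config an [ExperimentConfig-class] with
#'   `scenario: adaptive_exposure`.
#' @return list with `adaptive`, `constant` (each an arm result), pooled
#'   `summary`, `trackTable` and `logger`.
#' @export
runAdaptiveExposure <- function(config) {
  pops <- adaptiveExposurePopulations(config)
  adaptive <- runExposureArm(config, pops, adaptive = TRUE)
  constant <- runExposureArm(config, pops, adaptive = FALSE)
  target <- configValue(config, "control.target")
  settle <- 10L
  el <- adaptive$exposureLog
  cl <- constant$exposureLog
  tracked <- first <- last <- NA_real_
  if (!is.null(el))
    tracked <- mean(el$measured[el$frame >= settle], na.rm = TRUE)
  if (!is.null(cl)) {
    first <- mean(cl$measured[cl$frame == min(cl$frame)], na.rm = TRUE)
    last <- mean(cl$measured[cl$frame == max(cl$frame)], na.rm = TRUE)
  }
  summary <- list(
    time_avg_measured_after_settle = tracked,
    target = target,
    constant_decay_fraction = 1 - last / first,
    final_snr_adaptive = mean(adaptive$finalSnr),
    final_snr_constant = mean(constant$finalSnr))
  list(adaptive = adaptive, constant = constant, summary = summary,
       trackTable = adaptive$trackTable, truth = NULL,
       logger = adaptive$logger)
}

# ---------------------------------------------------------------------------
# characterization + fit
# ---------------------------------------------------------------------------

#' Default three-group characterisation light profiles
#'
#' Three qualitatively different binary profiles over `nSteps` measurement
#' intervals: a sustained step (steady-state level), an induction block
#' followed by darkness (a clean decay phase, which identifies the removal
#' rate), and alternating pulses (fast dynamics, which pin down the delay).
#'
#' @param nSteps number of 6-min intervals.
#' @param stepMin interval (min).
#' @param pulseMs pulse duration (ms).
#' @return list of three [LightProfile-class].
#' @export
characterizationProfiles <- function(nSteps = 100L, stepMin = 6,
                                     pulseMs = 1000) {
  list(
    LightProfile(rep(TRUE, nSteps), stepMin, pulseMs),
    LightProfile(seq_len(nSteps) <= nSteps %/% 3, stepMin, pulseMs),
    LightProfile(rep(c(TRUE, FALSE), length.out = nSteps), stepMin, pulseMs))
}

#' Characterisation scenario: simulate three-group data and refit the model
#'
#' Simulates population-mean fluorescence trajectories for three cell groups
#' under distinct binary light profiles from the deterministic model, adds
#' Gaussian measurement noise (5 % of the dynamic range), and refits
#' `k, b0, gamma` by profiled least squares with the delay on a 3-min grid.
#'
#' @param config an [ExperimentConfig-class] (model block + seed used).
#' @param nSteps number of measurement intervals simulated.
#' @param noiseFrac noise SD as a fraction of the dynamic range.
#' @return list with `fit` (see [fitDeterministic()]), `data`, `truth`
#'   (the generating parameter values in fluorescence units), `summary`.
#' @export
runCharacterization <- function(config, nSteps = 100L, noiseFrac = 0.05) {
  params <- configModelParams(config)
  stepMin <- configValue(config, "control.step_min")
  pulseMs <- configValue(config, "control.pulse_ms")
  profiles <- characterizationProfiles(nSteps, stepMin, pulseMs)
  horizon <- nSteps * stepMin
  tmeas <- seq(0, horizon, by = stepMin)
  clean <- lapply(profiles, function(lp) {
    tr <- simulateDeterministic(params, lp, horizon, dtMin = 3, p0 = 0)
    data.frame(time = tmeas,
               fluor = params@alpha *
                 tr$protein[match(tmeas, tr$time)])
  })
  rng <- range(unlist(lapply(clean, `[[`, "fluor")))
  sdNoise <- noiseFrac * diff(rng)
  streams <- rngStreams(configValue(config, "seed"))
  noisy <- withStream(streams, "characterization",
    lapply(clean, function(d) {
      d$fluor <- d$fluor + stats::rnorm(nrow(d), 0, sdNoise)
      d
    }))
  fit <- fitDeterministic(noisy, profiles, tauGrid = seq(0, 60, by = 3),
                          dtMin = 3)
  truth <- list(k = params@alpha * params@k, b0 = params@alpha * params@b0,
                gamma = params@gamma, tau = params@tau)
  summary <- list(tau_recovered_min = fit$params@tau,
                  tau_true_min = params@tau,
                  k_rel_err = abs(fit$params@k - truth$k) / truth$k,
                  gamma_rel_err = abs(fit$params@gamma - truth$gamma) /
                    truth$gamma)
  list(fit = fit, data = noisy, profiles = profiles, truth = truth,
       summary = summary, trackTable = NULL, logger = ExperimentLogger())
}

# ---------------------------------------------------------------------------
# MPC strategy comparison
# ---------------------------------------------------------------------------

#' Compare open-loop, population and single-cell MPC on a matched population
#'
#' Runs the three control strategies against stochastically simulated cells
#' (exact per-interval birth-death transitions) from identical seeds and
#' initial states. Population feedback filters the mean measurement with a
#' Kalman filter; single-cell feedback runs one FSP Bayesian filter and one
#' expected-absolute-deviation MPC per cell. Per-cell performance is the
#' time-averaged absolute deviation of the true fluorescence from target.
#'
#' Cells are not identical: each carries a lognormal expression-capacity
#' factor (CV `extrinsicCV`) scaling its production rates, and the whole
#' experiment carries one batch ("day") factor (CV `batchCV`) - while all
#' controllers use the nominal calibrated model, as in a real experiment
#' where one model, fitted on earlier data, serves a heterogeneous
#' population on a different day. Cell-to-cell variability is what only
#' single-cell feedback can compensate; the batch mismatch is what separates
#' any feedback from open-loop application of a precomputed profile (with a
#' perfect model and no disturbances, open loop would be optimal and the
#' comparison vacuous).
#'
#' @param config an [ExperimentConfig-class].
#' @param nCells number of cells.
#' @param nSteps number of measurement intervals.
#' @param strategies subset of `c("open", "population", "single")`.
#' @param extrinsicCV coefficient of variation of the per-cell expression
#'   capacity (0 = identical cells).
#' @param batchCV coefficient of variation of the per-experiment batch
#'   factor on expression capacity (0 = perfectly calibrated model).
#' @return list with `deviations` (cell x strategy matrix), `applied` light
#'   matrices, `trajectories` (true fluorescence per strategy), `summary`.
#' @export
runMpcComparison <- function(config, nCells = 100L, nSteps = 30L,
                             strategies = c("open", "population", "single"),
                             extrinsicCV = 0.35, batchCV = 0.15) {
  params <- configModelParams(config)
  v <- config@values
  stepMin <- v$control$step_min
  H <- v$control$horizon_steps
  target <- v$control$target_fluor
  D <- bufferLength(params@tau, stepMin)
  taskMse <- ControlTask(rep(target, nSteps + D + H), H, stepMin,
                         v$control$pulse_ms, cost = "mse")
  taskEad <- ControlTask(rep(target, nSteps + D + H), H, stepMin,
                         v$control$pulse_ms, cost = "ead")
  N <- as.integer(ceiling(8 * (params@b0 + params@k) / params@gamma))
  kernels <- NULL
  openProfile <- if ("open" %in% strategies || "population" %in% strategies)
    precomputeOpenLoop(params, taskMse, nSteps, p0 = 0) else NULL

  baseStreams <- rngStreams(v$seed)
  capacity <- withStream(baseStreams, "extrinsic", {
    sdlog <- sqrt(log(1 + extrinsicCV^2))
    sdBatch <- sqrt(log(1 + batchCV^2))
    batch <- stats::rlnorm(1, meanlog = -sdBatch^2 / 2, sdlog = sdBatch)
    batch * stats::rlnorm(nCells, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  })

  runStrategy <- function(mode) {
    streams <- rngStreams(v$seed)
    n <- rep(0L, nCells)
    applied <- matrix(FALSE, nCells, nSteps)
    fluorTrue <- matrix(NA_real_, nCells, nSteps)
    kal <- KalmanState(0, 0, params, stepMin)
    qScale <- 1 / nCells
    paramsMean <- params
    paramsMean@sigmaMeas <- params@sigmaMeas / sqrt(nCells)
    fsps <- NULL
    if (mode == "single") {
      if (is.null(kernels)) kernels <<- fspKernels(params, N, stepMin)
      fsps <- replicate(nCells, FspState(params, N = N, stepMin = stepMin),
                        simplify = FALSE)
    }
    for (t in seq_len(nSteps)) {
      u <- switch(mode,
        open = rep(openProfile@pulses[t], nCells),
        population = rep(mpcSelectDeterministic(kal, taskMse, params,
                                                currentStep = t - 1L)$apply,
                         nCells),
        single = vapply(fsps, function(f)
          mpcSelectSingleCell(f, taskEad, params, kernels,
                              currentStep = t - 1L)$apply, TRUE))
      applied[, t] <- u
      uProd <- if (t - D >= 1L) applied[, t - D] else rep(FALSE, nCells)
      for (i in seq_len(nCells)) {
        pi <- params
        pi@k <- params@k * capacity[i]
        pi@b0 <- params@b0 * capacity[i]
        n[i] <- withStream(streams, paste0("cell", i),
                           ssaIntervalStep(n[i], as.numeric(uProd[i]),
                                           stepMin, pi))
      }
      y <- withStream(streams, "meas",
                      params@alpha * n + stats::rnorm(nCells, 0,
                                                      params@sigmaMeas))
      fluorTrue[, t] <- params@alpha * n
      if (mode == "population") {
        a <- exp(-params@gamma * stepMin)
        b <- params@b0 + params@k * kal@inputBuffer[1]
        q <- (a * (1 - a) * max(kal@mean, 0) +
                b / params@gamma * (1 - a)) * qScale
        kal <- kalmanStep(kal, appliedLight = u[1], measurement = mean(y),
                          params = paramsMean, stepMin = stepMin, q = q)
      } else if (mode == "single") {
        for (i in seq_len(nCells)) {
          f <- fspPropagate(fsps[[i]], appliedLight = u[i], stepMin, params,
                            kernels)
          fsps[[i]] <- fspUpdate(f, y[i], params)
        }
      }
    }
    dev <- apply(fluorTrue, 1, function(x) controlPerformance(x, target))
    list(deviation = dev, applied = applied, fluorTrue = fluorTrue)
  }

  out <- lapply(stats::setNames(strategies, strategies), runStrategy)
  deviations <- vapply(out, `[[`, numeric(nCells), "deviation")
  summary <- as.list(apply(deviations, 2, stats::median))
  names(summary) <- paste0("median_dev_", names(summary))
  list(results = out, deviations = deviations, target = target,
       summary = summary, trackTable = NULL, logger = ExperimentLogger())
}

# ---------------------------------------------------------------------------
# recombination patterns (ring / islet)
# ---------------------------------------------------------------------------

#' Recombination targeting scenario (ring or islet)
#'
#' Full event-driven experiment: brightfield tracking every frame,
#' recombination-reporter imaging at the fluorescence cadence, target
#' selection per the configured mode (all cells ever inside a ring, or
#' dynamically selected isolated cells), eroded-mask DMD stimulation of all
#' targeted tracks at every stimulation tick, ground-truth recombination
#' with probability `p_rec` per effective stimulation, and endpoint
#' phenotype classification.
#'
#' @param config an [ExperimentConfig-class] with `scenario: recombination`.
#' @return list with `registry`, `endpoint` (see [classifyEndpoint()]),
#'   `trackTable`, `truth` (per-frame ground-truth snapshots), `scope`,
#'   `state`, `summary`.
#' @export
runRecombination <- function(config) {
  v <- config@values
  tg <- v$targeting
  streams <- rngStreams(v$seed)
  logger <- ExperimentLogger()
  recParams <- configRecombinationParams(config)
  pos <- v$positions[1]
  pops <- list()
  withStream(streams, "init",
    pops[[pos]] <- initPopulation(v$sample$n_cells, v$sample$image_shape,
                                  meanRadius = v$sample$mean_radius,
                                  growthRate = v$sample$growth_rate_per_min))
  scope <- VirtualMicroscope(configSampleParams(config), pops,
                             recParams = recParams, logger = logger,
                             streams = streams,
                             exposures = unlist(v$channels$exposures))
  state <- ExperimentState(positions = pos, channels = "CFP",
                           bfPeriodMin = v$periods$brightfield_min,
                           fluorEvery = as.integer(round(
                             v$periods$fluorescence_min /
                               v$periods$brightfield_min)),
                           logger = logger)
  state@analysisHooks <- list(makeSegmentationHook())
  center <- if (anyNA(tg$center)) (v$sample$image_shape - 1) / 2 else tg$center
  ring <- RingRegion(center, tg$r_inner, tg$r_outer)
  state@userData$registry <- TargetRegistry(
    periodMin = v$periods$fluorescence_min, pulseMs = v$control$pulse_ms)
  state@userData$skipped <- integer()

  select <- Event(
    id = "select-targets", recurrence = "always",
    trigger = function(s) !is.null(s@tracks[[pos]]) &&
      nrow(s@tracks[[pos]]$cells) > 0,
    effect = function(s, sc) {
      cells <- s@tracks[[pos]]$cells
      s@userData$registry <- if (tg$mode == "ring")
        ringUpdate(cells, ring, s@userData$registry, frame = s@frameIndex)
      else if (s@frameIndex %% s@fluorEvery == 0L)
        isletSelect(cells, s@userData$registry, dMin = tg$d_min,
                    maxNew = tg$max_new, frame = s@frameIndex)
      else s@userData$registry
      s
    })
  stimulate <- Event(
    id = "stimulate-targets", recurrence = "always",
    trigger = function(s) s@frameIndex %% s@fluorEvery == 0L &&
      nrow(s@userData$registry@targets) > 0 && !is.null(s@segs[[pos]]),
    effect = function(s, sc) {
      built <- buildStimulationMask(s@tracks[[pos]]$cells, s@segs[[pos]],
                                    s@userData$registry,
                                    erosionRadius = tg$erosion_radius,
                                    frame = s@frameIndex)
      if (length(built$skipped)) {
        s@userData$skipped <- union(s@userData$skipped, built$skipped)
        logRecord(s@logger, "targeting",
                  "targeted track absent this frame; stimulation skipped",
                  frame = s@frameIndex, severity = "warning",
                  payload = list(track_ids = built$skipped))
      }
      if (any(built$mask@pixels)) {
        dose <- dmdStimulate(sc, built$mask, position = pos)
        newPop <- withStream(sc@env$streams, "recombination",
          applyRecombination(getPopulation(sc, pos), dose, recParams,
                             clockMin = s@clockMin))
        setPopulation(sc, pos, newPop)
      }
      s
    })
  state <- registerEvent(state, select)
  state <- registerEvent(state, stimulate)

  truth <- NULL
  for (f in seq_len(v$frames)) {
    truth <- rbind(truth, truthSnapshot(getPopulation(scope, pos), f - 1L,
                                        scopeClock(scope)))
    state <- evaluateFrame(state, scope, jitterSd = 0.25,
                           partition = "binomial")
  }
  registry <- state@userData$registry
  tt <- state@userData$trackTable
  endpoint <- NULL
  if (!is.null(tt)) {
    lastFluor <- max(tt$frame[!is.na(tt$fluor_CFP)])
    final <- tt[tt$frame == lastFluor, ]
    fluor <- stats::setNames(final$fluor_CFP, final$track_id)
    endpoint <- classifyEndpoint(fluor, registry)
    tt$targeted <- tt$track_id %in% targetedIds(registry)
  }
  summary <- list(n_targeted = nrow(registry@targets),
                  n_recombined_truth = sum(getPopulation(scope, pos)$recombined),
                  n_outlier_targeted_not_recombined =
                    length(endpoint$targetedNotRecombined),
                  n_outlier_recombined_not_targeted =
                    length(endpoint$recombinedNotTargeted))
  list(registry = registry, endpoint = endpoint, trackTable = tt,
       truth = truth, scope = scope, state = state, summary = summary,
       logger = logger)
}

#' Match observed tracks to ground-truth cells
#'
#' Looks up each track's current centroid in the ground-truth label image.
#'
#' @param cells track table with `track_id`, `cx`, `cy`.
#' @param pop population data.frame.
#' @param shape image shape.
#' @return data.frame `track_id`, `cell_id` (0 where unmatched).
#' @export
matchTracksToTruth <- function(cells, pop, shape) {
  lab <- truthLabels(pop, shape)
  idx <- cbind(pmin(pmax(round(cells$cx) + 1, 1), shape[1]),
               pmin(pmax(round(cells$cy) + 1, 1), shape[2]))
  data.frame(track_id = cells$track_id, cell_id = lab[idx])
}
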