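# Virtual microscope: the hardware handle used by the event loop.
#
# Pure rendering/dosing functions (renderImage, dmdDose) implement the
# physics; the VirtualMicroscope class wraps them behind the same handle
# contract a real microscope module would expose (snap, set exposure,
# stimulate, advance time), with per-position sample state and logging.

CHANNELS <- c("brightfield", "GFP", "RFP", "CFP")

# internal: per-cell signal relevant to a fluorescence channel.
# GFP carries the light-driven reporter, RFP the membrane dye, CFP the
# recombination reporter.
channelSignal <- function(pop, channel, clockMin = 0, recParams = NULL) {
  switch(channel,
    GFP = pop$protein,
    RFP = pop$dye,
    CFP = if (is.null(recParams)) numeric(nrow(pop))
          else recReporterLevel(pop, clockMin, recParams),
    stop("unknown fluorescence channel: ", channel))
}

# internal: logical mask of one cell's ellipse footprint (0-based coords)
ellipseMask <- function(shape, cx, cy, a, b, theta) {
  bb <- ceiling(max(a, b)) + 1
  i0 <- max(0, floor(cx - bb)); i1 <- min(shape[1] - 1, ceiling(cx + bb))
  j0 <- max(0, floor(cy - bb)); j1 <- min(shape[2] - 1, ceiling(cy + bb))
  out <- matrix(FALSE, shape[1], shape[2])
  if (i1 < i0 || j1 < j0) return(out)
  ii <- i0:i1; jj <- j0:j1
  dx <- matrix(ii - cx, length(ii), length(jj))
  dy <- matrix(jj - cy, length(ii), length(jj), byrow = TRUE)
  xr <- (dx * cos(theta) + dy * sin(theta)) / a
  yr <- (-dx * sin(theta) + dy * cos(theta)) / b
  out[ii + 1, jj + 1] <- xr^2 + yr^2 <= 1
  out
}

#' Ground-truth label image of a population
#'
#' Rasterises every cell's ellipse into an integer image whose pixel values
#' are cell ids (later-placed cells win ties on the rare overlap pixels).
#' This is the oracle segmentation used by tests and by DMD dosing.
#'
#' @param pop population data.frame.
#' @param shape image shape (rows, cols).
#' @return integer matrix, 0 = background.
#' @export
truthLabels <- function(pop, shape) {
  lab <- matrix(0L, shape[1], shape[2])
  for (i in seq_len(nrow(pop))) {
    m <- ellipseMask(shape, pop$cx[i], pop$cy[i], pop$a[i], pop$b[i],
                     pop$theta[i])
    lab[m] <- pop$id[i]
  }
  lab
}

#' Render one camera image of a population
#'
#' Fluorescence channels: expected pixel value inside a cell is
#' `backgroundLevel + intensityGain * exposureMs * signal` (signals of
#' overlapping cells add). Brightfield: bright background with darker cell
#' interiors and a radial edge gradient, which makes threshold segmentation
#' well posed. Optional Poisson shot noise (mean = expected intensity) and
#' additive Gaussian read noise.
#'
#' @param pop population data.frame.
#' @param channel one of `"brightfield"`, `"GFP"`, `"RFP"`, `"CFP"`.
#' @param exposureMs exposure time (> 0, ms).
#' @param params a [VirtualSampleParams-class].
#' @param clockMin experiment time (min), used by the recombination reporter.
#' @param recParams optional [RecombinationParams-class].
#' @return numeric matrix (rows, cols) of pixel intensities.
#' @export
renderImage <- function(pop, channel, exposureMs, params, clockMin = 0,
                        recParams = NULL) {
  if (exposureMs <= 0) stop("exposureMs must be > 0")
  channel <- match.arg(channel, CHANNELS)
  shape <- params@imageShape
  if (channel == "brightfield") {
    bg <- 1000
    img <- matrix(bg, shape[1], shape[2])
    for (i in seq_len(nrow(pop))) {
      m <- ellipseMask(shape, pop$cx[i], pop$cy[i], pop$a[i], pop$b[i],
                       pop$theta[i])
      idx <- which(m)
      if (!length(idx)) next
      ij <- arrayInd(idx, shape) - 1
      dx <- ij[, 1] - pop$cx[i]; dy <- ij[, 2] - pop$cy[i]
      xr <- (dx * cos(pop$theta[i]) + dy * sin(pop$theta[i])) / pop$a[i]
      yr <- (-dx * sin(pop$theta[i]) + dy * cos(pop$theta[i])) / pop$b[i]
      rho <- sqrt(pmin(1, xr^2 + yr^2))
      img[idx] <- bg * (0.5 + 0.3 * rho)
    }
  } else {
    img <- matrix(params@backgroundLevel, shape[1], shape[2])
    sig <- channelSignal(pop, channel, clockMin, recParams)
    for (i in seq_len(nrow(pop))) {
      if (sig[i] == 0) next
      m <- ellipseMask(shape, pop$cx[i], pop$cy[i], pop$a[i], pop$b[i],
                       pop$theta[i])
      img[m] <- img[m] + params@intensityGain * exposureMs * sig[i]
    }
  }
  if (params@shotNoise)
    img <- matrix(stats::rpois(length(img), pmax(img, 0)), shape[1], shape[2])
  if (params@readNoiseSd > 0)
    img <- img + stats::rnorm(length(img), 0, params@readNoiseSd)
  pmax(img, 0)
}

#' Per-cell light dose delivered by a DMD stimulation mask
#'
#' The effective illumination field is the mask convolved with a Gaussian of
#' `bleedPsfSigma` px (DMD bleed-through). Each cell's dose is
#' `durationMs * intensity * mean(field over the cell's true footprint)`,
#' so an all-true mask delivers the full `durationMs * intensity` to every
#' cell and neighbours of a targeted cell receive partial doses.
#'
#' @param pop population data.frame.
#' @param mask a [StimulationMask-class].
#' @param params a [VirtualSampleParams-class].
#' @return named numeric vector of doses (names = cell ids).
#' @export
dmdDose <- function(pop, mask, params) {
  if (!identical(dim(mask@pixels), as.integer(params@imageShape)))
    stop("mask shape does not match the camera image shape")
  field <- mask@pixels * 1.0
  if (params@bleedPsfSigma > 0 && any(field > 0)) {
    field <- as.matrix(EBImage::gblur(field, sigma = params@bleedPsfSigma))
    field <- pmax(field, 0)   # FFT ringing can leave tiny negatives
  }
  dose <- numeric(nrow(pop))
  for (i in seq_len(nrow(pop))) {
    m <- ellipseMask(params@imageShape, pop$cx[i], pop$cy[i], pop$a[i],
                     pop$b[i], pop$theta[i])
    dose[i] <- if (any(m)) mean(field[m]) else 0
  }
  dose <- dose * mask@durationMs * mask@intensity
  names(dose) <- pop$id
  dose
}

# ---------------------------------------------------------------------------
# The stateful hardware handle
# ---------------------------------------------------------------------------

#' Virtual microscope handle
#'
#' Wraps the rendering and dosing physics behind the handle contract the
#' event loop expects from a hardware module: per-position sample state,
#' per-position per-channel exposures with clamped [setExposure()], image
#' snapping, DMD stimulation with a light-dose history, and sample time
#' advancing. All mutable state lives in the `env` slot.
#'
#' @slot env environment with fields `params`, `populations`, `exposures`,
#'   `clockMin`, `lightHistory`, `recParams`, `logger`, `streams`,
#'   `exposureBounds`.
#' @export
setClass("VirtualMicroscope", representation(env = "environment"))

#' @param sampleParams a [VirtualSampleParams-class].
#' @param populations named list of population data.frames (one per position).
#' @param recParams optional [RecombinationParams-class].
#' @param logger optional [ExperimentLogger-class].
#' @param streams optional RNG streams from [rngStreams()].
#' @param exposures named numeric of default per-channel exposures (ms).
#' @param exposureBounds hardware exposure limits (ms).
#' @rdname VirtualMicroscope-class
#' @export
VirtualMicroscope <- function(sampleParams, populations, recParams = NULL,
                              logger = NULL, streams = NULL,
                              exposures = c(brightfield = 20, GFP = 100,
                                            RFP = 100, CFP = 100),
                              exposureBounds = c(1, 5000)) {
  stopifnot(is.list(populations), length(names(populations)) == length(populations))
  env <- new.env(parent = emptyenv())
  env$params <- sampleParams
  env$populations <- populations
  env$exposures <- stats::setNames(
    rep(list(exposures), length(populations)), names(populations))
  env$clockMin <- 0
  env$lightHistory <- data.frame(frame = integer(), position = character(),
                                 cell_id = integer(), dose = numeric())
  env$recParams <- recParams
  env$logger <- if (is.null(logger)) ExperimentLogger() else logger
  env$streams <- streams
  env$exposureBounds <- exposureBounds
  new("VirtualMicroscope", env = env)
}

setMethod("show", "VirtualMicroscope", function(object) {
  e <- object@env
  cat("VirtualMicroscope:", length(e$populations), "position(s),",
      sum(vapply(e$populations, nrow, 0L)), "cells, clock =",
      e$clockMin, "min\n")
})

#' Positions of a virtual microscope
#' @param scope a [VirtualMicroscope-class].
#' @export
scopePositions <- function(scope) names(scope@env$populations)

#' Sample clock of a virtual microscope (minutes)
#' @param scope a [VirtualMicroscope-class].
#' @export
scopeClock <- function(scope) scope@env$clockMin

#' Ground-truth population at a position
#' @param scope a [VirtualMicroscope-class].
#' @param position position name.
#' @export
getPopulation <- function(scope, position = scopePositions(scope)[1]) {
  scope@env$populations[[position]]
}

#' Light-dose history recorded by the DMD
#' @param scope a [VirtualMicroscope-class].
#' @export
lightHistory <- function(scope) scope@env$lightHistory

#' Set a channel exposure on the microscope
#'
#' Out-of-bounds requests are clamped to the hardware limits and logged as
#' warnings; each position holds its own exposures.
#'
#' @param scope a [VirtualMicroscope-class].
#' @param channel channel name.
#' @param exposureMs requested exposure (ms).
#' @param position position name.
#' @param frame frame index for the log record.
#' @return the exposure actually set (ms), invisibly.
#' @export
setExposure <- function(scope, channel, exposureMs,
                        position = scopePositions(scope)[1], frame = NA_integer_) {
  channel <- match.arg(channel, CHANNELS)
  e <- scope@env
  b <- e$exposureBounds
  actual <- min(max(exposureMs, b[1]), b[2])
  if (actual != exposureMs)
    logRecord(e$logger, "microscope",
              sprintf("exposure request %.1f ms clamped to %.1f ms", exposureMs, actual),
              frame = frame, severity = "warning",
              payload = list(channel = channel, position = position))
  e$exposures[[position]][[channel]] <- actual
  logRecord(e$logger, "microscope", "exposure set", frame = frame,
            payload = list(channel = channel, position = position,
                           exposure_ms = actual))
  invisible(actual)
}

#' Current exposure of a channel
#' @inheritParams setExposure
#' @export
getExposure <- function(scope, channel, position = scopePositions(scope)[1]) {
  scope@env$exposures[[position]][[channel]]
}

#' Snap an image at a position
#'
#' Renders the current ground truth with the stored (or overriding) exposure,
#' drawing camera noise from the `"camera"` RNG stream when streams are
#' attached.
#'
#' @param scope a [VirtualMicroscope-class].
#' @param channel channel name.
#' @param position position name.
#' @param exposureMs optional exposure override (ms).
#' @param frame frame index for the log record.
#' @return numeric image matrix.
#' @export
snapImage <- function(scope, channel, position = scopePositions(scope)[1],
                      exposureMs = NULL, frame = NA_integer_) {
  e <- scope@env
  if (is.null(exposureMs)) exposureMs <- getExposure(scope, channel, position)
  pop <- e$populations[[position]]
  render <- function()
    renderImage(pop, channel, exposureMs, e$params, e$clockMin, e$recParams)
  img <- if (is.null(e$streams)) render() else
    withStream(e$streams, "camera", render())
  logRecord(e$logger, "microscope", "image acquired", frame = frame,
            payload = list(channel = channel, position = position,
                           exposure_ms = exposureMs))
  img
}

#' Stimulate a position with a DMD mask
#'
#' Computes per-cell doses via [dmdDose()], appends them to the microscope's
#' light history and log, and returns them.
#'
#' @param scope a [VirtualMicroscope-class].
#' @param mask a [StimulationMask-class].
#' @param position position name.
#' @return named numeric vector of per-cell doses.
#' @export
dmdStimulate <- function(scope, mask, position = scopePositions(scope)[1]) {
  e <- scope@env
  dose <- dmdDose(e$populations[[position]], mask, e$params)
  if (length(dose))
    e$lightHistory <- rbind(e$lightHistory,
      data.frame(frame = mask@frameIndex, position = position,
                 cell_id = as.integer(names(dose)), dose = as.numeric(dose)))
  logRecord(e$logger, "microscope", "DMD stimulation", frame = mask@frameIndex,
            payload = list(position = position, pixels = sum(mask@pixels),
                           duration_ms = mask@durationMs,
                           total_dose = sum(dose)))
  dose
}

#' Advance the sample by one time step
#'
#' Steps every position's population ([stepPopulation()]) under the
#' `"population"` RNG stream and advances the sample clock.
#'
#' @param scope a [VirtualMicroscope-class].
#' @param dtMin step (min).
#' @param ... passed to [stepPopulation()].
#' @export
advanceSample <- function(scope, dtMin, ...) {
  e <- scope@env
  stepAll <- function() {
    for (pos in names(e$populations))
      e$populations[[pos]] <- stepPopulation(
        e$populations[[pos]], dtMin, clockMin = e$clockMin,
        dyeDecayRate = e$params@dyeDecayRate, recParams = e$recParams,
        imageShape = e$params@imageShape, ...)
  }
  if (is.null(e$streams)) stepAll() else
    withStream(e$streams, "population", stepAll())
  e$clockMin <- e$clockMin + dtMin
  invisible(scope)
}

#' Replace the population at a position
#' @param scope a [VirtualMicroscope-class].
#' @param position position name.
#' @param value population data.frame.
#' @export
setPopulation <- function(scope, position, value) {
  scope@env$populations[[position]] <- value
  invisible(scope)
}
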