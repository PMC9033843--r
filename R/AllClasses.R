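#' @import methods
NULL

# ---------------------------------------------------------------------------
# Gene expression model parameters
# ---------------------------------------------------------------------------

#' Parameters of the light-driven gene expression model
#'
#' One-stage birth--death model of reporter expression with a deterministic
#' input delay: protein is produced at rate `b0 + k * u(t - tau)` and degraded
#' (degradation plus dilution by growth) at rate `gamma * P`. The input
#' `u` is the binary light activation of the interval (a short saturating
#' pulse maps to `u = 1` for its whole measurement interval). Fluorescence
#' is `alpha * P` plus Gaussian measurement noise.
#'
#' @slot k maximal light-induced production rate (molecules/min).
#' @slot b0 basal production rate (molecules/min).
#' @slot gamma degradation + dilution rate (1/min); default `log(2)/90`,
#'   i.e. an effective protein half-life matching a ~90 min generation time.
#' @slot tau delay between light application and effective production (min);
#'   dominated by fluorophore maturation, default 36.
#' @slot alpha fluorescence units per molecule.
#' @slot sigmaMeas measurement noise standard deviation (fluorescence units).
#' @export
setClass("GeneExpressionParams",
  representation(k = "numeric", b0 = "numeric", gamma = "numeric",
                 tau = "numeric", alpha = "numeric", sigmaMeas = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@k < 0 || object@b0 < 0) msg <- c(msg, "k and b0 must be >= 0")
    if (object@gamma <= 0) msg <- c(msg, "gamma must be > 0")
    if (object@tau < 0) msg <- c(msg, "tau must be >= 0")
    if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @param k,b0,gamma,tau,alpha,sigmaMeas see slot documentation.
#' @return A `GeneExpressionParams` object.
#' @rdname GeneExpressionParams-class
#' @export
GeneExpressionParams <- function(k = 0.25, b0 = 0.01, gamma = log(2) / 90,
                                 tau = 36, alpha = 100, sigmaMeas = 50) {
  new("GeneExpressionParams", k = k, b0 = b0, gamma = gamma, tau = tau,
      alpha = alpha, sigmaMeas = sigmaMeas)
}

setMethod("show", "GeneExpressionParams", function(object) {
  cat("GeneExpressionParams: k =", object@k, "b0 =", object@b0,
      "gamma =", signif(object@gamma, 4), "tau =", object@tau,
      "alpha =", object@alpha, "sigmaMeas =", object@sigmaMeas, "\n")
})

# ---------------------------------------------------------------------------
# Light stimulation profile
# ---------------------------------------------------------------------------

#' Binary light stimulation profile
#'
#' A sequence of binary decisions, one per measurement interval: a short
#' saturating light pulse (default 1000 ms) is either applied or not at the
#' start of each interval (default 6 min). A pulse activates transcription
#' for its whole interval (`u = 1`).
#'
#' @slot stepMin measurement interval in minutes.
#' @slot pulses logical vector, one entry per interval.
#' @slot pulseMs pulse duration in milliseconds.
#' @export
setClass("LightProfile",
  representation(stepMin = "numeric", pulses = "logical", pulseMs = "numeric"),
  validity = function(object) {
    if (object@stepMin <= 0) return("stepMin must be > 0")
    if (object@pulseMs <= 0) return("pulseMs must be > 0")
    if (anyNA(object@pulses)) return("pulses must not contain NA")
    TRUE
  })

#' @param pulses logical vector of per-interval decisions.
#' @param stepMin,pulseMs see slot documentation.
#' @rdname LightProfile-class
#' @export
LightProfile <- function(pulses, stepMin = 6, pulseMs = 1000) {
  new("LightProfile", stepMin = stepMin, pulses = as.logical(pulses),
      pulseMs = pulseMs)
}

setMethod("show", "LightProfile", function(object) {
  cat("LightProfile:", length(object@pulses), "intervals of", object@stepMin,
      "min;", object@pulseMs, "ms pulses; pattern",
      paste(as.integer(object@pulses), collapse = ""), "\n")
})

#' Per-interval light activation of a profile
#'
#' Maps the binary pulse decisions to the activation level `u` used by the
#' expression models: a pulse saturates the photosensitive transcription
#' factor for its interval, so `u = 1` when a pulse is applied, else 0.
#'
#' @param light a [LightProfile-class].
#' @return numeric vector of activations in `[0, 1]`.
#' @export
lightActivation <- function(light) {
  stopifnot(is(light, "LightProfile"))
  as.numeric(light@pulses)
}

# ---------------------------------------------------------------------------
# Recombination parameters
# ---------------------------------------------------------------------------

#' Parameters of the light-driven recombination cascade
#'
#' Light above a dose threshold expresses a recombinase which switches the
#' cell irreversibly to a reporter-expressing state with probability `pRec`
#' per stimulation; unstimulated cells may recombine spontaneously. After
#' `reporterDelay` minutes the recombination reporter ramps up and the cell's
#' growth rate is multiplied by `growthFactorPost` (slow-growth phenotype).
#'
#' @slot pRec per-stimulation recombination probability given dose >= threshold.
#' @slot pSpont spontaneous recombination probability per frame.
#' @slot doseThreshold minimal effective dose (ms * relative intensity).
#' @slot reporterDelay minutes between recombination and reporter rise.
#' @slot growthFactorPost growth-rate multiplier (< 1) after recombination.
#' @export
setClass("RecombinationParams",
  representation(pRec = "numeric", pSpont = "numeric", doseThreshold = "numeric",
                 reporterDelay = "numeric", growthFactorPost = "numeric"),
  validity = function(object) {
    if (object@pRec < 0 || object@pRec > 1) return("pRec must be in [0,1]")
    if (object@pSpont < 0 || object@pSpont > 1) return("pSpont must be in [0,1]")
    if (object@doseThreshold < 0) return("doseThreshold must be >= 0")
    TRUE
  })

#' @param pRec,pSpont,doseThreshold,reporterDelay,growthFactorPost see slots.
#' @rdname RecombinationParams-class
#' @export
RecombinationParams <- function(pRec = 0.9, pSpont = 0, doseThreshold = 200,
                                reporterDelay = 60, growthFactorPost = 0.3) {
  new("RecombinationParams", pRec = pRec, pSpont = pSpont,
      doseThreshold = doseThreshold, reporterDelay = reporterDelay,
      growthFactorPost = growthFactorPost)
}

# ---------------------------------------------------------------------------
# Virtual sample / camera parameters
# ---------------------------------------------------------------------------

#' Virtual sample and camera model parameters
#'
#' Rendering model of the simulated microscope. Inside a cell the expected
#' pixel value of a fluorescence channel is
#' `backgroundLevel + intensityGain * exposure_ms * signal`, where `signal`
#' is the channel-relevant molecular state of the cell (reporter molecules,
#' dye level, or recombination reporter). Optional Poisson shot noise uses
#' the expected intensity as its mean; Gaussian read noise is additive.
#' Stimulation masks are blurred with a Gaussian of `bleedPsfSigma` pixels
#' to emulate DMD illumination bleed-through.
#'
#' @slot imageShape integer (rows, cols), at least 64 x 64.
#' @slot pixelSize microns per pixel.
#' @slot backgroundLevel camera background (intensity units).
#' @slot readNoiseSd additive Gaussian read noise SD.
#' @slot shotNoise logical, Poisson shot noise on/off.
#' @slot dyeDecayRate global exponential decay rate of the dye signal (1/min).
#' @slot bleedPsfSigma Gaussian sigma (px) applied to stimulation masks.
#' @slot intensityGain intensity units per (molecule * ms of exposure).
#' @export
setClass("VirtualSampleParams",
  representation(imageShape = "integer", pixelSize = "numeric",
                 backgroundLevel = "numeric", readNoiseSd = "numeric",
                 shotNoise = "logical", dyeDecayRate = "numeric",
                 bleedPsfSigma = "numeric", intensityGain = "numeric"),
  validity = function(object) {
    if (length(object@imageShape) != 2 || any(object@imageShape < 64))
      return("imageShape must be two integers >= 64")
    if (object@dyeDecayRate < 0 || object@readNoiseSd < 0 ||
        object@bleedPsfSigma < 0 || object@intensityGain < 0)
      return("rates, noise and gain must be >= 0")
    TRUE
  })

#' @param imageShape,pixelSize,backgroundLevel,readNoiseSd,shotNoise see slots.
#' @param dyeDecayRate,bleedPsfSigma,intensityGain see slots.
#' @rdname VirtualSampleParams-class
#' @export
VirtualSampleParams <- function(imageShape = c(256L, 256L), pixelSize = 0.1,
                                backgroundLevel = 50, readNoiseSd = 2,
                                shotNoise = TRUE, dyeDecayRate = 0,
                                bleedPsfSigma = 2, intensityGain = 1) {
  new("VirtualSampleParams", imageShape = as.integer(imageShape),
      pixelSize = pixelSize, backgroundLevel = backgroundLevel,
      readNoiseSd = readNoiseSd, shotNoise = shotNoise,
      dyeDecayRate = dyeDecayRate, bleedPsfSigma = bleedPsfSigma,
      intensityGain = intensityGain)
}

# ---------------------------------------------------------------------------
# Stimulation mask
# ---------------------------------------------------------------------------

#' Spatial light stimulation mask for the DMD
#'
#' @slot pixels logical matrix, same shape as the camera image.
#' @slot durationMs pulse duration (> 0).
#' @slot intensity relative intensity in `[0, 1]`.
#' @slot frameIndex frame at which the mask is applied.
#' @export
setClass("StimulationMask",
  representation(pixels = "matrix", durationMs = "numeric",
                 intensity = "numeric", frameIndex = "integer"),
  validity = function(object) {
    if (!is.logical(object@pixels)) return("pixels must be a logical matrix")
    if (object@durationMs <= 0) return("durationMs must be > 0")
    if (object@intensity < 0 || object@intensity > 1)
      return("intensity must be in [0,1]")
    TRUE
  })

#' @param pixels,durationMs,intensity,frameIndex see slots.
#' @rdname StimulationMask-class
#' @export
StimulationMask <- function(pixels, durationMs = 1000, intensity = 1,
                            frameIndex = 0L) {
  new("StimulationMask", pixels = pixels, durationMs = durationMs,
      intensity = intensity, frameIndex = as.integer(frameIndex))
}

# ---------------------------------------------------------------------------
# Estimation states
# ---------------------------------------------------------------------------

#' Kalman filter state for the population ("average cell") model
#'
#' Scalar linear-Gaussian state (protein level in molecule units) with an
#' input buffer holding the light activations applied over the last `tau`
#' minutes; the delay is honoured by reading the oldest buffer entry during
#' prediction (input augmentation rather than state augmentation).
#'
#' @slot mean estimated protein level (molecules).
#' @slot variance estimation variance (>= 0).
#' @slot inputBuffer activations of the last `ceil(tau/stepMin)` intervals,
#'   oldest first.
#' @export
setClass("KalmanState",
  representation(mean = "numeric", variance = "numeric",
                 inputBuffer = "numeric"),
  validity = function(object) {
    if (object@variance < 0) return("variance must be >= 0")
    TRUE
  })

#' @param mean,variance see slots.
#' @param params a [GeneExpressionParams-class]; sets the buffer length.
#' @param stepMin measurement interval (min).
#' @rdname KalmanState-class
#' @export
KalmanState <- function(mean = 0, variance = 0, params, stepMin = 6) {
  nbuf <- bufferLength(params@tau, stepMin)
  new("KalmanState", mean = mean, variance = variance,
      inputBuffer = rep(0, nbuf))
}

setMethod("show", "KalmanState", function(object) {
  cat("KalmanState: mean =", signif(object@mean, 5),
      "sd =", signif(sqrt(object@variance), 4),
      "buffer =", paste(object@inputBuffer, collapse = ""), "\n")
})

#' Finite-state-projection filter state for the single-cell model
#'
#' Truncated probability distribution over protein copy number 0..N plus the
#' probability mass that has leaked past the truncation boundary. Between
#' measurement updates `sum(p) + leaked == 1`; a measurement update
#' renormalises and resets the leak.
#'
#' @slot N truncation bound (maximum copy number represented).
#' @slot p probability vector over `0:N`.
#' @slot leaked accumulated truncation mass.
#' @slot inputBuffer as in [KalmanState-class].
#' @export
setClass("FspState",
  representation(N = "integer", p = "numeric", leaked = "numeric",
                 inputBuffer = "numeric"),
  validity = function(object) {
    if (length(object@p) != object@N + 1L)
      return("p must have length N + 1")
    if (any(object@p < -1e-12)) return("p must be >= 0")
    if (abs(sum(object@p) + object@leaked - 1) > 1e-6)
      return("sum(p) + leaked must equal 1")
    TRUE
  })

#' @param N truncation bound; defaults to 8x the maximal stationary mean.
#' @param p initial distribution (defaults to all mass at 0).
#' @param params a [GeneExpressionParams-class].
#' @param stepMin measurement interval (min).
#' @rdname FspState-class
#' @export
FspState <- function(params, N = NULL, p = NULL, stepMin = 6) {
  if (is.null(N))
    N <- as.integer(ceiling(8 * (params@b0 + params@k) / params@gamma))
  N <- as.integer(N)
  if (is.null(p)) p <- c(1, rep(0, N))
  nbuf <- bufferLength(params@tau, stepMin)
  new("FspState", N = N, p = p, leaked = 1 - sum(p),
      inputBuffer = rep(0, nbuf))
}

setMethod("show", "FspState", function(object) {
  m <- sum(0:object@N * object@p) / max(sum(object@p), .Machine$double.eps)
  cat("FspState: N =", object@N, "mean =", signif(m, 5),
      "leaked =", signif(object@leaked, 3), "\n")
})

#' Posterior mean copy number of an FSP state
#' @param state an [FspState-class].
#' @return numeric scalar.
#' @export
fspMean <- function(state) {
  s <- sum(state@p)
  if (s <= 0) return(NA_real_)
  sum(0:state@N * state@p) / s
}

# internal: input delay buffer length
bufferLength <- function(tau, stepMin) max(1L, as.integer(ceiling(tau / stepMin)))

# ---------------------------------------------------------------------------
# Control tasks and controllers
# ---------------------------------------------------------------------------

#' Receding-horizon control task
#'
#' Defines the target fluorescence trajectory, the horizon and the cost used
#' by the model predictive controllers. Candidate inputs are all `2^H` binary
#' pulse sequences of length `H`.
#'
#' @slot targetProfile target fluorescence per measurement step (a.u.);
#'   extended by its last value beyond its end.
#' @slot horizonSteps H, number of intervals in the receding horizon
#'   (default 4, i.e. 24 min of 6-min steps).
#' @slot stepMin measurement interval (min).
#' @slot pulseMs pulse duration (ms).
#' @slot cost `"mse"` (mean squared deviation, population controller) or
#'   `"ead"` (expected absolute deviation, single-cell controller).
#' @export
setClass("ControlTask",
  representation(targetProfile = "numeric", horizonSteps = "integer",
                 stepMin = "numeric", pulseMs = "numeric", cost = "character"),
  validity = function(object) {
    if (object@horizonSteps < 1L) return("horizonSteps must be >= 1")
    if (!object@cost %in% c("mse", "ead"))
      return("cost must be 'mse' or 'ead'")
    TRUE
  })

#' @param targetProfile,horizonSteps,stepMin,pulseMs,cost see slots.
#' @rdname ControlTask-class
#' @export
ControlTask <- function(targetProfile, horizonSteps = 4L, stepMin = 6,
                        pulseMs = 1000, cost = "mse") {
  new("ControlTask", targetProfile = targetProfile,
      horizonSteps = as.integer(horizonSteps), stepMin = stepMin,
      pulseMs = pulseMs, cost = cost)
}

#' Constant-step adaptive exposure controller parameters
#'
#' If the measured mean cell fluorescence is below `target - deadband` the
#' exposure is increased by `step` ms, above `target + deadband` decreased by
#' `step` ms, and clamped to `[eMin, eMax]`.
#'
#' @slot target target fluorescence (a.u.), default 3000.
#' @slot deadband half-width of the no-action band (a.u.).
#' @slot step constant exposure increment (ms).
#' @slot eMin,eMax exposure bounds (ms).
#' @export
setClass("ExposureControllerParams",
  representation(target = "numeric", deadband = "numeric", step = "numeric",
                 eMin = "numeric", eMax = "numeric"),
  validity = function(object) {
    if (object@eMin >= object@eMax) return("eMin must be < eMax")
    if (object@step <= 0) return("step must be > 0")
    if (object@deadband < 0) return("deadband must be >= 0")
    TRUE
  })

#' @param target,deadband,step,eMin,eMax see slots.
#' @rdname ExposureControllerParams-class
#' @export
ExposureControllerParams <- function(target = 3000, deadband = 150, step = 5,
                                     eMin = 10, eMax = 1000) {
  new("ExposureControllerParams", target = target, deadband = deadband,
      step = step, eMin = eMin, eMax = eMax)
}

# ---------------------------------------------------------------------------
# Targeting
# ---------------------------------------------------------------------------

#' Annular (ring) targeting region
#'
#' @slot center (row, col) centre in pixels.
#' @slot rInner,rOuter inner/outer radii in pixels, `0 <= rInner < rOuter`.
#' @export
setClass("RingRegion",
  representation(center = "numeric", rInner = "numeric", rOuter = "numeric"),
  validity = function(object) {
    if (length(object@center) != 2) return("center must be (row, col)")
    if (object@rInner < 0 || object@rInner >= object@rOuter)
      return("need 0 <= rInner < rOuter")
    TRUE
  })

#' @param center,rInner,rOuter see slots.
#' @rdname RingRegion-class
#' @export
RingRegion <- function(center, rInner, rOuter) {
  new("RingRegion", center = as.numeric(center), rInner = rInner,
      rOuter = rOuter)
}

#' Registry of light-targeted cell tracks
#'
#' Targeting is permanent: once a track is added it is stimulated (1 s pulse
#' by default) at every stimulation tick (every 6 min by default) until the
#' end of the experiment.
#'
#' @slot targets data.frame with columns `track_id`, `first_target_frame`.
#' @slot periodMin stimulation period (min).
#' @slot pulseMs stimulation pulse duration (ms).
#' @export
setClass("TargetRegistry",
  representation(targets = "data.frame", periodMin = "numeric",
                 pulseMs = "numeric"),
  validity = function(object) {
    if (!all(c("track_id", "first_target_frame") %in% colnames(object@targets)))
      return("targets needs columns track_id, first_target_frame")
    if (anyDuplicated(object@targets$track_id))
      return("track ids must be unique in the registry")
    TRUE
  })

#' @param periodMin,pulseMs see slots.
#' @rdname TargetRegistry-class
#' @export
TargetRegistry <- function(periodMin = 6, pulseMs = 1000) {
  new("TargetRegistry",
      targets = data.frame(track_id = integer(), first_target_frame = integer()),
      periodMin = periodMin, pulseMs = pulseMs)
}

#' Targeted track ids of a registry
#' @param registry a [TargetRegistry-class].
#' @return integer vector of track ids.
#' @export
targetedIds <- function(registry) registry@targets$track_id

setMethod("show", "TargetRegistry", function(object) {
  cat("TargetRegistry:", nrow(object@targets), "targeted tracks;",
      object@pulseMs, "ms pulse every", object@periodMin, "min\n")
})
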