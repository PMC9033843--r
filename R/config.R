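# Experiment configuration: YAML schema with typed defaults, unknown-key
# rejection (with a nearest-key suggestion) and cross-field validation.

# schema: default values define both structure and types; NA marks
# "no default, optional" fields typed by the prototype value class
configDefaults <- function() list(
  scenario = "adaptive_exposure",
  seed = 1L,
  frames = 60L,
  output_dir = NA_character_,
  positions = "pos1",
  periods = list(brightfield_min = 3, fluorescence_min = 6),
  channels = list(fluorescence = "GFP",
                  exposures = list(brightfield = 20, GFP = 100, RFP = 100,
                                   CFP = 100)),
  sample = list(n_cells = 50L, image_shape = c(256L, 256L),
                background_level = 50, read_noise_sd = 2, shot_noise = TRUE,
                dye_half_life_min = NA_real_, bleed_psf_sigma = 2,
                intensity_gain = 1, mean_radius = 7,
                growth_rate_per_min = log(2) / 90, dye0 = 0),
  model = list(k = 0.25, b0 = 0.01, gamma = log(2) / 90, tau_min = 36,
               alpha = 100, sigma_meas = 50),
  control = list(target = 3000, deadband = 150, step_ms = 5, e_min = 10,
                 e_max = 1000, horizon_steps = 4L, step_min = 6,
                 pulse_ms = 1000, target_fluor = 1500, n_groups = 3L),
  targeting = list(mode = "ring", center = NA_real_, r_inner = 55,
                   r_outer = 85, d_min = 45, max_new = 1L,
                   erosion_radius = 2, p_rec = 0.9, p_spont = 0,
                   dose_threshold = 200, reporter_delay_min = 60,
                   growth_factor_post = 0.3, rec_plateau = 30,
                   rec_ramp_min = 60))

#' Validated experiment configuration
#'
#' @slot values fully resolved, typed configuration list.
#' @export
setClass("ExperimentConfig", representation(values = "list"))

setMethod("show", "ExperimentConfig", function(object) {
  v <- object@values
  cat("ExperimentConfig: scenario", v$scenario, "| seed", v$seed, "|",
      v$frames, "frames of", v$periods$brightfield_min, "min\n")
})

#' Fetch a configuration value by dot path
#'
#' @param config an [ExperimentConfig-class].
#' @param path e.g. `"model.tau_min"`.
#' @export
configValue <- function(config, path) {
  v <- config@values
  for (k in strsplit(path, ".", fixed = TRUE)[[1]]) v <- v[[k]]
  v
}

# internal: merge user values over defaults, rejecting unknown keys
mergeConfig <- function(user, defaults, prefix = "") {
  if (is.null(user)) return(defaults)
  for (key in names(user)) {
    full <- paste0(prefix, key)
    if (!key %in% names(defaults)) {
      near <- names(defaults)[which.min(utils::adist(key, names(defaults)))]
      stop("unknown configuration key '", full, "'",
           if (length(near)) paste0("; did you mean '", prefix, near, "'?"),
           call. = FALSE)
    }
    d <- defaults[[key]]
    u <- user[[key]]
    if (is.list(d) && !is.null(names(d))) {
      if (!is.list(u)) stop("configuration key '", full, "' must be a mapping")
      defaults[[key]] <- mergeConfig(u, d, paste0(full, "."))
    } else {
      coerced <- switch(class(d)[1],
                        integer = as.integer(u),
                        numeric = as.numeric(u),
                        logical = as.logical(u),
                        character = as.character(u),
                        u)
      if (anyNA(coerced) && !anyNA(u))
        stop("configuration key '", full, "' has the wrong type")
      defaults[[key]] <- coerced
    }
  }
  defaults
}

#' Validate a raw configuration into an [ExperimentConfig-class]
#'
#' Accepts a YAML string, a file path, or an already-parsed list. All fields
#' are typed and defaulted; unknown keys are rejected with the nearest valid
#' key suggested; cross-field invariants (period divisibility, scenario
#' names, positive durations) are enforced before any acquisition starts.
#'
#' @param raw YAML text, a file path, or a named list.
#' @return an [ExperimentConfig-class].
#' @export
validateConfig <- function(raw) {
  user <- if (is.list(raw)) raw
          else if (file.exists(raw)) yaml::read_yaml(raw)
          else yaml::yaml.load(raw)
  if (is.null(user)) user <- list()
  v <- mergeConfig(user, configDefaults())
  scen <- c("adaptive_exposure", "characterization", "mpc_comparison",
            "recombination")
  if (!v$scenario %in% scen)
    stop("unknown scenario '", v$scenario, "'; expected one of: ",
         paste(scen, collapse = ", "), call. = FALSE)
  bp <- v$periods$brightfield_min
  fp <- v$periods$fluorescence_min
  if (bp <= 0 || fp <= 0) stop("periods must be positive", call. = FALSE)
  if (abs(fp / bp - round(fp / bp)) > 1e-9)
    stop("periods.fluorescence_min (", fp, ") must be a multiple of ",
         "periods.brightfield_min (", bp, ")", call. = FALSE)
  if (v$frames < 0L) stop("frames must be >= 0", call. = FALSE)
  bad <- setdiff(v$channels$fluorescence, c("GFP", "RFP", "CFP"))
  if (length(bad))
    stop("unknown channel name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (length(v$sample$image_shape) != 2L || any(v$sample$image_shape < 64L))
    stop("sample.image_shape must be two integers >= 64", call. = FALSE)
  if (!v$targeting$mode %in% c("ring", "islet"))
    stop("targeting.mode must be 'ring' or 'islet'", call. = FALSE)
  new("ExperimentConfig", values = v)
}

# internal: model/controller objects from a config
configModelParams <- function(config) {
  m <- config@values$model
  GeneExpressionParams(k = m$k, b0 = m$b0, gamma = m$gamma, tau = m$tau_min,
                       alpha = m$alpha, sigmaMeas = m$sigma_meas)
}

configSampleParams <- function(config) {
  s <- config@values$sample
  VirtualSampleParams(
    imageShape = s$image_shape, backgroundLevel = s$background_level,
    readNoiseSd = s$read_noise_sd, shotNoise = s$shot_noise,
    dyeDecayRate = if (is.na(s$dye_half_life_min)) 0
                   else log(2) / s$dye_half_life_min,
    bleedPsfSigma = s$bleed_psf_sigma, intensityGain = s$intensity_gain)
}

configRecombinationParams <- function(config) {
  t <- config@values$targeting
  RecombinationParams(pRec = t$p_rec, pSpont = t$p_spont,
                      doseThreshold = t$dose_threshold,
                      reporterDelay = t$reporter_delay_min,
                      growthFactorPost = t$growth_factor_post)
}
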