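# Event engine: the reactive core.
#
# An experiment is a main acquisition loop interleaving imaging, online
# analysis, trigger evaluation and effect application. Events are the unit
# of reactivity: a trigger predicate over the experiment state plus an
# effect that may mutate state, drive the hardware handle, or register new
# events (visible from the next frame's evaluation pass). Execution is
# sequential-equivalent: effects run in registration order, and a failing
# effect is logged and isolated without aborting the frame loop.

#' A reactive event: trigger + effect
#'
#' @slot id unique identifier within the registry.
#' @slot trigger `function(state)` returning `TRUE`/`FALSE`.
#' @slot effect `function(state, scope)` returning the (possibly modified)
#'   state; may call hardware methods on `scope` and register new events.
#' @slot recurrence `"once"` (deactivated after first firing), `"always"`,
#'   or `"until"` (active while `frame <= untilFrame`).
#' @slot untilFrame last active frame for `"until"` recurrence.
#' @slot createdAtFrame frame at which the event was registered.
#' @slot active whether the event is still evaluated.
#' @export
setClass("Event",
  representation(id = "character", trigger = "function", effect = "function",
                 recurrence = "character", untilFrame = "integer",
                 createdAtFrame = "integer", active = "logical"),
  validity = function(object) {
    if (!object@recurrence %in% c("once", "always", "until"))
      return("recurrence must be 'once', 'always' or 'until'")
    if (object@recurrence == "until" && is.na(object@untilFrame))
      return("'until' recurrence needs untilFrame")
    TRUE
  })

#' @param id,trigger,effect,recurrence,untilFrame,createdAtFrame see slots.
#' @rdname Event-class
#' @export
Event <- function(id, trigger, effect, recurrence = "once",
                  untilFrame = NA_integer_, createdAtFrame = 0L) {
  new("Event", id = id, trigger = trigger, effect = effect,
      recurrence = recurrence, untilFrame = as.integer(untilFrame),
      createdAtFrame = as.integer(createdAtFrame), active = TRUE)
}

setMethod("show", "Event", function(object) {
  cat("Event '", object@id, "' (", object@recurrence, ", ",
      if (object@active) "active" else "inactive", ")\n", sep = "")
})

#' Experiment state threaded through the acquisition loop
#'
#' @slot frameIndex 0-based frame counter (strictly increasing).
#' @slot clockMin minutes since start (`frameIndex * bfPeriodMin`).
#' @slot bfPeriodMin brightfield (backbone) frame period, min.
#' @slot fluorEvery fluorescence channels acquired every this many frames.
#' @slot positions position names.
#' @slot channels fluorescence channels acquired.
#' @slot latestImages list keyed `"position/channel"`.
#' @slot segs latest [SegmentationResult-class] per position.
#' @slot tracks track state per position (see [initTracks()]).
#' @slot channelExposures per-position named exposure vectors (ms), mirrored
#'   from the hardware each frame.
#' @slot events the event registry (list of [Event-class]).
#' @slot analysisHooks list of `function(state, scope)` run after acquisition.
#' @slot logger the shared [ExperimentLogger-class].
#' @slot userData free-form list for effects and controllers.
#' @export
setClass("ExperimentState",
  representation(frameIndex = "integer", clockMin = "numeric",
                 bfPeriodMin = "numeric", fluorEvery = "integer",
                 positions = "character", channels = "character",
                 latestImages = "list", segs = "list", tracks = "list",
                 channelExposures = "list", events = "list",
                 analysisHooks = "list", logger = "ExperimentLogger",
                 userData = "list"))

#' @param positions position names.
#' @param channels fluorescence channels to acquire.
#' @param bfPeriodMin brightfield period (min).
#' @param fluorEvery fluorescence cadence in brightfield frames.
#' @param logger an [ExperimentLogger-class] (a fresh one by default).
#' @rdname ExperimentState-class
#' @export
ExperimentState <- function(positions = "pos1", channels = character(),
                            bfPeriodMin = 3, fluorEvery = 2L,
                            logger = ExperimentLogger()) {
  new("ExperimentState", frameIndex = 0L, clockMin = 0,
      bfPeriodMin = bfPeriodMin, fluorEvery = as.integer(fluorEvery),
      positions = positions, channels = channels, latestImages = list(),
      segs = list(), tracks = list(), channelExposures = list(),
      events = list(), analysisHooks = list(), logger = logger,
      userData = list())
}

setMethod("show", "ExperimentState", function(object) {
  cat("ExperimentState: frame", object@frameIndex, "(",
      object@clockMin, "min ),", length(object@events), "events,",
      length(object@positions), "position(s)\n")
})

#' Frame index accessor
#' @param state an [ExperimentState-class].
#' @export
frameIndex <- function(state) state@frameIndex

#' Register an event in the experiment state
#'
#' Duplicate ids are rejected: the registry is left unchanged and an error
#' record is logged (the experiment continues).
#'
#' @param state an [ExperimentState-class].
#' @param event an [Event-class].
#' @return updated state.
#' @export
registerEvent <- function(state, event) {
  ids <- vapply(state@events, function(e) e@id, "")
  if (event@id %in% ids) {
    logRecord(state@logger, "events",
              paste0("duplicate event id rejected: ", event@id),
              frame = state@frameIndex, severity = "error")
    return(state)
  }
  ev <- event
  ev@createdAtFrame <- state@frameIndex
  state@events <- c(state@events, list(ev))
  logRecord(state@logger, "events", paste0("event registered: ", ev@id),
            frame = state@frameIndex,
            payload = list(recurrence = ev@recurrence))
  state
}

#' Ids of active events
#' @param state an [ExperimentState-class].
#' @export
activeEventIds <- function(state) {
  ids <- vapply(state@events, function(e) if (e@active) e@id else NA_character_, "")
  ids[!is.na(ids)]
}

# internal: fluorescence channels due at a frame
dueChannels <- function(state) {
  due <- "brightfield"
  if (length(state@channels) && state@frameIndex %% state@fluorEvery == 0L)
    due <- c(due, state@channels)
  due
}

#' Run one frame of the acquisition loop
#'
#' Acquires the channels due this frame at every position, runs the analysis
#' hooks, evaluates all triggers of the events active at the start of the
#' pass on the updated state, applies the effects of true triggers in
#' registration order (an effect exception is logged and isolated), advances
#' the sample and the frame counter. Events registered by an effect are
#' evaluated from the next frame.
#'
#' @param state an [ExperimentState-class].
#' @param scope a [VirtualMicroscope-class] (the hardware handle).
#' @param advance whether to advance the sample clock by one frame period
#'   (population growth, dye decay).
#' @param ... passed to [advanceSample()].
#' @return updated state.
#' @export
evaluateFrame <- function(state, scope, advance = TRUE, ...) {
  fr <- state@frameIndex
  due <- dueChannels(state)
  for (pos in state@positions) {
    for (ch in due) {
      img <- snapImage(scope, ch, position = pos, frame = fr)
      state@latestImages[[paste(pos, ch, sep = "/")]] <- img
    }
    state@channelExposures[[pos]] <- unlist(scope@env$exposures[[pos]])
  }
  for (hook in state@analysisHooks) {
    state <- tryCatch(hook(state, scope), error = function(e) {
      logRecord(state@logger, "analysis",
                paste0("analysis hook failed: ", conditionMessage(e)),
                frame = fr, severity = "error")
      state
    })
  }
  snapshot <- seq_along(state@events)
  for (i in snapshot) {
    ev <- state@events[[i]]
    if (!ev@active) next
    if (ev@recurrence == "until" && fr > ev@untilFrame) {
      state@events[[i]]@active <- FALSE
      next
    }
    fired <- tryCatch(isTRUE(ev@trigger(state)), error = function(e) {
      logRecord(state@logger, "events",
                paste0("trigger error in '", ev@id, "': ", conditionMessage(e)),
                frame = fr, severity = "error")
      FALSE
    })
    if (!fired) next
    state <- tryCatch({
      s2 <- ev@effect(state, scope)
      logRecord(state@logger, "events", paste0("effect applied: ", ev@id),
                frame = fr, payload = list(event = ev@id))
      s2
    }, error = function(e) {
      logRecord(state@logger, "events",
                paste0("effect error in '", ev@id, "': ", conditionMessage(e)),
                frame = fr, severity = "error", payload = list(event = ev@id))
      state
    })
    if (ev@recurrence == "once") {
      # the effect may have altered the registry; deactivate by id
      for (j in seq_along(state@events))
        if (state@events[[j]]@id == ev@id) state@events[[j]]@active <- FALSE
    }
  }
  if (advance) advanceSample(scope, state@bfPeriodMin, ...)
  state@frameIndex <- fr + 1L
  state@clockMin <- state@frameIndex * state@bfPeriodMin
  logRecord(state@logger, "core", "frame completed", frame = fr)
  state
}

#' Standard online-analysis hook: segment, track, quantify
#'
#' Segments the latest brightfield image of every position, links the result
#' to the existing tracks, and attaches per-channel mean fluorescence for
#' the channels acquired this frame. Results accumulate in
#' `state@userData$trackTable` (one row per cell per frame).
#'
#' @param minArea segmentation minimum area (px^2).
#' @param maxDisp tracking gate (px).
#' @return a hook `function(state, scope)`.
#' @export
makeSegmentationHook <- function(minArea = 30, maxDisp = 12) {
  function(state, scope) {
    fr <- state@frameIndex
    fluorDue <- length(state@channels) && fr %% state@fluorEvery == 0L
    for (pos in state@positions) {
      bf <- state@latestImages[[paste(pos, "brightfield", sep = "/")]]
      if (is.null(bf)) next
      seg <- segmentCells(bf, minArea = minArea)
      st <- state@tracks[[pos]]
      st <- if (is.null(st)) initTracks(seg, frame = fr)
            else linkTracks(st, seg, maxDisp = maxDisp, frame = fr)
      state@tracks[[pos]] <- st
      state@segs[[pos]] <- seg
      if (nrow(st$cells)) {
        rows <- data.frame(frame = fr, position = pos,
                           track_id = st$cells$track_id,
                           label = st$cells$label, cx = st$cells$cx,
                           cy = st$cells$cy, area = st$cells$area)
        for (ch in state@channels) {
          col <- paste0("fluor_", ch)
          rows[[col]] <- NA_real_
          if (fluorDue) {
            fimg <- state@latestImages[[paste(pos, ch, sep = "/")]]
            if (!is.null(fimg)) {
              q <- quantifyCells(seg, fimg)
              rows[[col]] <- q$mean_fluor[match(st$cells$label, q$label)]
            }
          }
        }
        state@userData$trackTable <-
          rbind(state@userData$trackTable, rows)
      }
      logRecord(state@logger, "analysis", "frame analysed", frame = fr,
                payload = list(position = pos, cells = nCells(seg),
                               lost = length(st$lost %||% integer())))
    }
    state
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
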