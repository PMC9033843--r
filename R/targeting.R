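# Single-cell light-targeting strategies for the recombination case study:
# ring-region targeting (every cell ever seen inside an annulus), islet
# selection (cells far from any previously-targeted cell), per-cell eroded
# stimulation masks, and endpoint phenotype classification.

#' Add tracks currently inside a ring region to the target registry
#'
#' Any track whose current centroid lies in the annulus is targeted;
#' targeting is permanent (a cell that later leaves the ring stays
#' targeted).
#'
#' @param cells current-frame track table (`track_id`, `cx`, `cy`; e.g.
#'   `state$tracks[[pos]]$cells`).
#' @param region a [RingRegion-class].
#' @param registry a [TargetRegistry-class].
#' @param frame current frame (recorded for new targets).
#' @return updated registry.
#' @export
ringUpdate <- function(cells, region, registry, frame = NA_integer_) {
  if (nrow(cells) == 0L) return(registry)
  d <- sqrt((cells$cx - region@center[1])^2 + (cells$cy - region@center[2])^2)
  inside <- d >= region@rInner & d <= region@rOuter
  newIds <- setdiff(cells$track_id[inside], registry@targets$track_id)
  if (length(newIds))
    registry@targets <- rbind(registry@targets,
      data.frame(track_id = newIds, first_target_frame = as.integer(frame)))
  registry
}

#' Select isolated cells ("islets") for targeting
#'
#' Candidates are visited in deterministic order: descending distance to the
#' nearest currently-targeted cell (with an empty registry, distance to the
#' nearest other cell), ties by ascending track id. A candidate is added iff
#' its distance to every targeted cell's current centroid - including cells
#' added earlier in this call - exceeds `dMin`; at most `maxNew` additions
#' per call.
#'
#' @param cells current-frame track table (`track_id`, `cx`, `cy`).
#' @param registry a [TargetRegistry-class].
#' @param dMin minimal separation (px, > 0).
#' @param maxNew cap on additions per call.
#' @param frame current frame.
#' @return updated registry.
#' @export
isletSelect <- function(cells, registry, dMin, maxNew = 1L,
                        frame = NA_integer_) {
  if (dMin <= 0) stop("dMin must be > 0")
  if (nrow(cells) == 0L || maxNew < 1L) return(registry)
  targeted <- cells[cells$track_id %in% registry@targets$track_id, ,
                    drop = FALSE]
  cand <- cells[!cells$track_id %in% registry@targets$track_id, ,
                drop = FALSE]
  if (nrow(cand) == 0L) return(registry)
  nearest <- function(x, y, pts) {
    if (nrow(pts) == 0L) return(Inf)
    min(sqrt((pts$cx - x)^2 + (pts$cy - y)^2))
  }
  refs <- if (nrow(targeted)) targeted else cells
  dN <- vapply(seq_len(nrow(cand)), function(i) {
    pts <- refs[refs$track_id != cand$track_id[i], , drop = FALSE]
    nearest(cand$cx[i], cand$cy[i], pts)
  }, 0)
  ord <- order(-dN, cand$track_id)
  added <- 0L
  sel <- targeted[, c("cx", "cy"), drop = FALSE]
  for (i in ord) {
    if (added >= maxNew) break
    if (nearest(cand$cx[i], cand$cy[i], sel) > dMin) {
      registry@targets <- rbind(registry@targets,
        data.frame(track_id = cand$track_id[i],
                   first_target_frame = as.integer(frame)))
      sel <- rbind(sel, data.frame(cx = cand$cx[i], cy = cand$cy[i]))
      added <- added + 1L
    }
  }
  registry
}

#' Build the DMD stimulation mask for the targeted cells
#'
#' Union of the eroded segmentation masks of all targeted tracks present in
#' the current frame. Targeted tracks with no current-frame mask (tracking
#' loss) are skipped and reported.
#'
#' @param cells current-frame track table (`track_id`, `label`).
#' @param seg current [SegmentationResult-class].
#' @param registry a [TargetRegistry-class].
#' @param erosionRadius per-cell mask erosion (px).
#' @param frame frame index stamped on the mask.
#' @param intensity relative light intensity.
#' @return list: `mask` (a [StimulationMask-class]), `skipped` (track ids of
#'   targeted tracks absent this frame).
#' @export
buildStimulationMask <- function(cells, seg, registry, erosionRadius = 2,
                                 frame = 0L, intensity = 1) {
  shape <- dim(seg@labelImage)
  px <- matrix(FALSE, shape[1], shape[2])
  ids <- registry@targets$track_id
  present <- cells[cells$track_id %in% ids, , drop = FALSE]
  skipped <- setdiff(ids, present$track_id)
  for (i in seq_len(nrow(present))) {
    cellMask <- seg@labelImage == present$label[i]
    px <- px | erodeMask(cellMask, erosionRadius)
  }
  list(mask = StimulationMask(px, durationMs = registry@pulseMs,
                              intensity = intensity, frameIndex = frame),
       skipped = skipped)
}

#' Classify endpoint recombination phenotypes
#'
#' A track is called recombined iff its final reporter fluorescence exceeds
#' the threshold. Returns the per-track calls, the fluorescence
#' distributions of targeted vs non-targeted cells, and the two outlier
#' lists (targeted-but-not-recombined, recombined-but-not-targeted).
#'
#' @param finalFluor named numeric vector of final reporter fluorescence,
#'   names = track ids.
#' @param registry a [TargetRegistry-class].
#' @param threshold classification threshold (a.u.); by default the midpoint
#'   between the min and max observed values (synthetic endpoints are
#'   bimodal by construction).
#' @return list with `table` (track_id, fluor, targeted, recombined),
#'   `targetedFluor`, `nonTargetedFluor`, `targetedNotRecombined`,
#'   `recombinedNotTargeted`.
#' @export
classifyEndpoint <- function(finalFluor, registry, threshold = NULL) {
  ids <- as.integer(names(finalFluor))
  if (is.null(threshold))
    threshold <- (min(finalFluor) + max(finalFluor)) / 2
  targeted <- ids %in% registry@targets$track_id
  recombined <- as.numeric(finalFluor) > threshold
  tab <- data.frame(track_id = ids, fluor = as.numeric(finalFluor),
                    targeted = targeted, recombined = recombined)
  list(table = tab,
       threshold = threshold,
       targetedFluor = tab$fluor[targeted],
       nonTargetedFluor = tab$fluor[!targeted],
       targetedNotRecombined = tab$track_id[targeted & !recombined],
       recombinedNotTargeted = tab$track_id[recombined & !targeted])
}
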