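# Frame-to-frame cell tracking.
#
# Linking is a globally-minimal rectangular assignment on squared centroid
# displacements, gated at maxDisp, solved exactly by a shortest augmenting
# path algorithm on the standard padded (tracks + dummies) x (cells +
# dummies) cost matrix: a track matched to a dummy goes absent, a cell
# matched to a dummy is a birth.

#' Minimal-cost assignment of a square cost matrix
#'
#' Exact Jonker--Volgenant-style shortest augmenting path solver (O(n^3)).
#'
#' @param cost square numeric matrix (finite entries).
#' @return integer vector `a` with `a[i]` the column assigned to row `i`.
#' @export
solveAssignment <- function(cost) {
  n <- nrow(cost)
  if (n == 0L) return(integer())
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 1L
    minv <- rep(Inf, n + 1); used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]; p[j0] <- p[j1]; j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0L) ans[p[j]] <- j - 1L
  ans
}

#' Start a track state from a first segmentation
#'
#' @param seg a [SegmentationResult-class].
#' @param frame frame index.
#' @return a track state: list with `frame`, `cells` (data.frame `track_id`,
#'   `label`, `cx`, `cy`, `area`) and `nextId`.
#' @export
initTracks <- function(seg, frame = 0L) {
  n <- nCells(seg)
  list(frame = as.integer(frame),
       cells = data.frame(track_id = seq_len(n), label = seg@table$label,
                          cx = seg@table$cx, cy = seg@table$cy,
                          area = seg@table$area),
       nextId = n + 1L)
}

#' Link a new frame's segmentation to existing tracks
#'
#' Globally-minimal assignment between previous track centroids and current
#' label centroids under squared-displacement cost; pairs farther than
#' `maxDisp` are never linked. Unmatched current labels start new tracks
#' (births, fresh never-reused ids); unmatched previous tracks go absent.
#' Ties are resolved deterministically by the solver.
#'
#' @param state track state from [initTracks()] or a previous call.
#' @param seg current frame's [SegmentationResult-class].
#' @param maxDisp gating displacement (px).
#' @param frame current frame index.
#' @return updated track state; `state$lost` holds the track ids that went
#'   absent this frame.
#' @export
linkTracks <- function(state, seg, maxDisp = 10, frame = state$frame + 1L) {
  prev <- state$cells
  curr <- seg@table
  np <- nrow(prev); nc <- nrow(curr)
  assignedTrack <- rep(NA_integer_, nc)
  if (np > 0L && nc > 0L) {
    d2 <- outer(prev$cx, curr$cx, "-")^2 + outer(prev$cy, curr$cy, "-")^2
    B <- maxDisp^2 + 1          # cost of going absent / being born
    FORBID <- 4 * B + 1e6       # worse than any pair of dummy moves
    link <- ifelse(d2 <= maxDisp^2, d2, FORBID)
    n <- np + nc
    cost <- matrix(0, n, n)     # dummy-dummy corner stays 0
    cost[seq_len(np), seq_len(nc)] <- link
    cost[seq_len(np), nc + seq_len(np)] <- FORBID
    cost[cbind(seq_len(np), nc + seq_len(np))] <- B
    cost[np + seq_len(nc), seq_len(nc)] <- FORBID
    cost[cbind(np + seq_len(nc), seq_len(nc))] <- B
    a <- solveAssignment(cost)
    for (i in seq_len(np)) {
      j <- a[i]
      if (j <= nc && d2[i, j] <= maxDisp^2)
        assignedTrack[j] <- prev$track_id[i]
    }
  }
  nextId <- state$nextId
  births <- which(is.na(assignedTrack))
  if (length(births)) {
    assignedTrack[births] <- nextId + seq_along(births) - 1L
    nextId <- nextId + length(births)
  }
  cells <- data.frame(track_id = assignedTrack, label = curr$label,
                      cx = curr$cx, cy = curr$cy, area = curr$area)
  lost <- setdiff(prev$track_id, assignedTrack)
  list(frame = as.integer(frame), cells = cells, nextId = nextId, lost = lost)
}
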