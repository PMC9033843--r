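# Online image analysis: threshold segmentation of synthetic brightfield
# images, per-cell fluorescence quantification, SNR, and mask erosion for
# targeted stimulation.

#' Segmentation result
#'
#' @slot labelImage integer matrix; 0 is background, labels are contiguous
#'   positive integers.
#' @slot table data.frame with one row per label: `label`, `cx`, `cy`
#'   (0-based centroid, px), `area` (px^2).
#' @export
setClass("SegmentationResult",
  representation(labelImage = "matrix", table = "data.frame"),
  validity = function(object) {
    labs <- sort(unique(as.integer(object@labelImage)))
    labs <- labs[labs > 0]
    if (length(labs) && !identical(labs, seq_along(labs)))
      return("labels must be contiguous positive integers")
    if (nrow(object@table) != length(labs))
      return("table rows must match label count")
    TRUE
  })

setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult:", nrow(object@table), "cells; mean area",
      if (nrow(object@table)) signif(mean(object@table$area), 4) else NA, "px^2\n")
})

#' Number of segmented cells
#' @param seg a [SegmentationResult-class].
#' @export
nCells <- function(seg) nrow(seg@table)

#' Segment a brightfield image
#'
#' Otsu threshold on the inverted (dark-cells-on-bright-background)
#' brightfield image, hole filling, connected components, and removal of
#' components below `minArea`. Components touching the image border are
#' discarded by default: clipped cells have biased centroids and areas,
#' which would corrupt tracking and quantification. Labels are relabelled
#' to be contiguous.
#'
#' @param image 2-D numeric matrix (brightfield).
#' @param minArea minimal component area kept (px^2).
#' @param dropBorder drop components touching the image border.
#' @return a [SegmentationResult-class].
#' @export
segmentCells <- function(image, minArea = 30, dropBorder = TRUE) {
  if (length(dim(image)) != 2L) stop("segmentCells expects a 2-D image")
  inv <- max(image) - image
  rng <- range(inv)
  if (rng[2] - rng[1] < .Machine$double.eps) {
    return(new("SegmentationResult",
               labelImage = matrix(0L, nrow(image), ncol(image)),
               table = data.frame(label = integer(), cx = numeric(),
                                  cy = numeric(), area = numeric())))
  }
  norm <- (inv - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(norm))
  bw <- EBImage::fillHull(norm > th)
  lab <- EBImage::bwlabel(bw)
  lab <- as.matrix(EBImage::imageData(lab))
  storage.mode(lab) <- "integer"
  if (dropBorder) {
    edge <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    lab[lab %in% edge[edge > 0L]] <- 0L
  }
  relabelFiltered(lab, minArea)
}

# internal: drop small components, relabel contiguously, tabulate centroids
relabelFiltered <- function(lab, minArea) {
  counts <- tabulate(lab[lab > 0L])
  keep <- which(counts >= minArea)
  map <- integer(length(counts))
  map[keep] <- seq_along(keep)
  pos <- lab > 0L
  lab[pos] <- map[lab[pos]]
  tab <- if (length(keep)) {
    idx <- which(lab > 0L)
    l <- lab[idx]
    ij <- arrayInd(idx, dim(lab)) - 1  # 0-based (row, col)
    data.frame(label = seq_along(keep),
               cx = as.numeric(rowsum(ij[, 1], l) / tabulate(l)),
               cy = as.numeric(rowsum(ij[, 2], l) / tabulate(l)),
               area = as.numeric(tabulate(l)))
  } else {
    data.frame(label = integer(), cx = numeric(), cy = numeric(),
               area = numeric())
  }
  new("SegmentationResult", labelImage = lab, table = tab)
}

#' Segmentation result from ground-truth cell geometry
#'
#' Builds a [SegmentationResult-class] directly from the simulator's truth
#' (no imaging, no noise); the oracle counterpart of [segmentCells()].
#'
#' @param pop population data.frame.
#' @param shape image shape (rows, cols).
#' @return list with the `seg` result and `ids`, the cell id of each label.
#' @export
truthSegmentation <- function(pop, shape) {
  lab <- truthLabels(pop, shape)
  ids <- sort(unique(as.integer(lab[lab > 0L])))
  map <- integer(if (length(ids)) max(ids) else 0L)
  map[ids] <- seq_along(ids)
  pos <- lab > 0L
  lab[pos] <- map[lab[pos]]
  res <- relabelFiltered(lab, 1L)
  list(seg = res, ids = ids)
}

#' Mean fluorescence per segmented cell
#'
#' A cell's fluorescence is the mean pixel intensity of the fluorescence
#' image over the cell's pixels.
#'
#' @param seg a [SegmentationResult-class].
#' @param fluorImage numeric matrix, same shape as the label image.
#' @return data.frame with columns `label` and `mean_fluor` (empty if there
#'   are no labels).
#' @export
quantifyCells <- function(seg, fluorImage) {
  if (!identical(dim(seg@labelImage), dim(fluorImage)))
    stop("fluorescence image shape does not match the label image")
  if (nCells(seg) == 0L)
    return(data.frame(label = integer(), mean_fluor = numeric()))
  idx <- which(seg@labelImage > 0L)
  l <- seg@labelImage[idx]
  data.frame(label = sort(unique(l)),
             mean_fluor = as.numeric(rowsum(fluorImage[idx], l) / tabulate(l)))
}

#' Signal-to-noise ratio of a fluorescence image
#'
#' Mean intensity over all cell pixels divided by mean intensity over
#' background pixels. The background excludes a 3-px dilation of the cell
#' masks to avoid halo contamination.
#'
#' @param seg a [SegmentationResult-class].
#' @param fluorImage numeric matrix.
#' @param dilateRadius halo exclusion radius (px).
#' @return scalar SNR.
#' @export
snrRatio <- function(seg, fluorImage, dilateRadius = 3) {
  cells <- seg@labelImage > 0L
  if (!any(cells)) stop("snrRatio needs at least one segmented cell")
  halo <- if (dilateRadius > 0)
    as.matrix(EBImage::dilate(cells,
      EBImage::makeBrush(2L * as.integer(dilateRadius) + 1L, "disc"))) > 0
  else cells
  bg <- !halo
  if (!any(bg)) stop("no background pixels left after halo exclusion")
  mbg <- mean(fluorImage[bg])
  if (mbg == 0) stop("background mean is zero; SNR undefined")
  mean(fluorImage[cells]) / mbg
}

#' Erode a boolean mask by a disk
#'
#' Morphological erosion by a disk of the given radius, used to shrink
#' per-cell stimulation regions so that DMD bleed-through does not hit
#' neighbouring cells. If erosion empties the mask, the single pixel nearest
#' the mask centroid is kept so every targeted cell still receives light.
#'
#' @param mask logical matrix.
#' @param radius erosion radius (px, >= 0).
#' @return logical matrix.
#' @export
erodeMask <- function(mask, radius) {
  if (radius < 0) stop("radius must be >= 0")
  if (radius == 0 || !any(mask)) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(ceiling(radius)) + 1L, "disc")
  out <- as.matrix(EBImage::erode(mask * 1, brush)) > 0.5
  if (!any(out)) {
    idx <- which(mask)
    ij <- arrayInd(idx, dim(mask))
    ctr <- colMeans(ij)
    nearest <- idx[which.min((ij[, 1] - ctr[1])^2 + (ij[, 2] - ctr[2])^2)]
    out <- matrix(FALSE, nrow(mask), ncol(mask))
    out[nearest] <- TRUE
  }
  out
}
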