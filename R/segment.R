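#' Segment cells from a background-corrected phase map
#'
#' Two-level segmentation. Cells are detected with an Otsu threshold on the
#' phase values, hole filling, distance-transform seeding and watershed
#' splitting of touching cells. Because the phase profile of a rod-shaped
#' cell falls off smoothly toward the true outline (the optical path length
#' is a chord through the cell body), the Otsu level sits well inside the
#' boundary; each watershed label is therefore grown out to a low outline
#' level — a fraction of the cell's robust peak phase, floored above the
#' background noise scale — so areas and section widths track the physical
#' cell outline. Border-touching cells are dropped, as are cells below the
#' minimum area.
#'
#' @param map a background-corrected [phase_map()].
#' @param min_area_um2 minimum cell area, µm².
#' @param frame frame id stored with the mask.
#' @param outline_frac outline level as a fraction of the 98th-percentile
#'   foreground phase.
#' @param noise_mult outline level floor, in units of the robust background
#'   noise scale (MAD).
#' @return integer label matrix (0 = background) of class `label_mask` with
#'   attributes `pixel_size`, `threshold` (outline level, radians) and
#'   `frame`.
#' @export
segment_cells <- function(map, min_area_um2 = 2, frame = 1L,
                          outline_frac = 0.12, noise_mult = 4) {
  if (!map$background_corrected)
    qc_log("segmenting a phase map that is not background-corrected")
  v <- map$phase
  rng <- range(v)
  if (rng[2] <= rng[1]) {
    qc_log("phase map has no contrast; returning empty mask")
    return(empty_mask(v, map$pixel_size, frame, rng[2]))
  }
  vn <- (v - rng[1]) / (rng[2] - rng[1])
  thr_n <- EBImage::otsu(EBImage::Image(vn), range = c(0, 1))
  thr <- rng[1] + thr_n * (rng[2] - rng[1])
  bw <- v > thr
  if (!any(bw)) {
    qc_log("no foreground above Otsu threshold; returning empty mask")
    return(empty_mask(v, map$pixel_size, frame, thr))
  }
  bwi <- EBImage::fillHull(EBImage::Image(bw * 1))
  dm <- EBImage::distmap(bwi)
  seeds <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1, ext = 1))
  seeds <- matrix(as.integer(seeds), nrow(v), ncol(v))
  # outline level: fraction of robust peak phase, floored above noise
  peak <- stats::quantile(v[bw], 0.98, names = FALSE)
  noise <- stats::mad(v[!bw])
  level <- max(outline_frac * peak, noise_mult * noise)
  bw_low <- EBImage::fillHull(EBImage::Image((v > level) * 1))
  lab <- EBImage::imageData(EBImage::propagate(
    EBImage::Image(vn), EBImage::Image(seeds), mask = bw_low))
  lab <- matrix(as.integer(lab), nrow(v), ncol(v))
  thr <- level
  # drop border-touching labels
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labels <- setdiff(border_labels, 0L)
  if (length(border_labels)) {
    qc_log("dropping %d border-touching label(s)", length(border_labels))
    lab[lab %in% border_labels] <- 0L
  }
  # minimum-area filter and consecutive relabeling
  min_px <- min_area_um2 / map$pixel_size^2
  tab <- table(lab[lab > 0])
  keep <- as.integer(names(tab))[tab >= min_px]
  lab[!(lab %in% keep)] <- 0L
  lab <- matrix(match(lab, c(0L, keep), nomatch = 1L) - 1L, nrow(v), ncol(v))
  structure(lab, pixel_size = map$pixel_size, threshold = thr,
            frame = frame, class = "label_mask")
}

empty_mask <- function(v, pixel_size, frame, thr) {
  structure(matrix(0L, nrow(v), ncol(v)), pixel_size = pixel_size,
            threshold = thr, frame = frame, class = "label_mask")
}

#' Sub-pixel cell contours by marching squares
#'
#' Extracts closed iso-contours of the phase map at the segmentation
#' threshold, restricted to each label. Vertices are linearly interpolated
#' between pixel centers (sub-pixel resolution); coordinates are physical µm
#' with pixel centers at `(index + 0.5) * pixel_size` (0-based indices).
#'
#' @param mask a `label_mask` from [segment_cells()].
#' @param map the [phase_map()] the mask was derived from.
#' @param level contour level; defaults to the mask's Otsu threshold.
#' @return named list of contours, one per label: each a list with `xy`
#'   (closed polygon matrix, columns x, y in µm; last vertex != first) and
#'   `label`.
#' @export
cell_contours <- function(mask, map, level = NULL) {
  if (is.null(level)) level <- attr(mask, "threshold")
  px <- attr(mask, "pixel_size")
  labels <- setdiff(sort(unique(as.vector(mask))), 0L)
  ry <- (seq_len(nrow(mask)) - 0.5) * px
  rx <- (seq_len(ncol(mask)) - 0.5) * px
  base <- min(map$phase)
  out <- list()
  for (l in labels) {
    z <- map$phase
    z[unclass(mask) != l] <- base    # suppress everything outside this label
    cl <- grDevices::contourLines(x = ry, y = rx, z = z, levels = level)
    if (!length(cl)) { qc_log("label %d produced no contour", l); next }
    # keep the longest closed loop
    lens <- vapply(cl, function(cc) length(cc$x), 0)
    cc <- cl[[which.max(lens)]]
    xy <- cbind(x = cc$y, y = cc$x)   # contourLines x runs over rows (our y)
    if (all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
    out[[as.character(l)]] <- list(xy = xy, label = l)
  }
  out
}

polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Lightweight per-label summary of a segmented frame
#'
#' Centroids, areas and bounding boxes only — sufficient for lineage
#' tracking when full morphometry is not needed.
#'
#' @param map a background-corrected [phase_map()].
#' @param frame frame id.
#' @param min_area_um2 segmentation minimum area.
#' @return data.frame with `frame`, `label`, `centroid_x`, `centroid_y`,
#'   `area_um2`, `bbox_*` (µm).
#' @export
segment_summary <- function(map, frame = 1L, min_area_um2 = 2) {
  mask <- segment_cells(map, min_area_um2 = min_area_um2, frame = frame)
  px <- attr(mask, "pixel_size")
  labels <- setdiff(sort(unique(as.vector(mask))), 0L)
  rows <- lapply(labels, function(l) {
    idx <- which(unclass(mask) == l, arr.ind = TRUE)
    data.frame(frame = frame, label = l,
               centroid_x = mean((idx[, 2] - 0.5) * px),
               centroid_y = mean((idx[, 1] - 0.5) * px),
               area_um2 = nrow(idx) * px^2,
               bbox_xmin = min((idx[, 2] - 1) * px), bbox_xmax = max(idx[, 2] * px),
               bbox_ymin = min((idx[, 1] - 1) * px), bbox_ymax = max(idx[, 1] * px))
  })
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
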