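#' Calibration scale from a mean-phase time series
#'
#' During calibration-standard timepoints the medium carries a known
#' concentration of standard (e.g. 100 mg/mL BSA), which reduces the phase
#' contrast of every cell. The scale (radians per mg/mL) is the drop in mean
#' cell phase at each calibration frame — relative to the mean of its flanking
#' non-calibration frames — divided by the standard concentration; multiple
#' calibration frames are averaged.
#'
#' @param mean_phase per-frame mean cell phase shift, radians.
#' @param calib_frames indices of calibration-standard frames.
#' @param concentration standard concentration, mg/mL.
#' @return object of class `calibration_scale`: list with `scale` (radians
#'   per mg/mL), `standard_concentration`, `frames_used`, `per_frame` scales.
#' @export
compute_calibration_scale <- function(mean_phase, calib_frames, concentration) {
  stopifnot(length(calib_frames) >= 1, concentration > 0,
            all(calib_frames >= 1), all(calib_frames <= length(mean_phase)))
  normal <- setdiff(seq_along(mean_phase), calib_frames)
  per <- vapply(calib_frames, function(f) {
    lo <- normal[normal < f]
    hi <- normal[normal > f]
    if (!length(lo) && !length(hi))
      stop("calibration frame has no non-calibration neighbor")
    flank <- c(if (length(lo)) mean_phase[max(lo)],
               if (length(hi)) mean_phase[min(hi)])
    if (length(flank) == 1)
      qc_log("calibration frame %d has a neighbor on one side only", f)
    (mean(flank) - mean_phase[f]) / concentration
  }, 0)
  if (any(per <= 0))
    stop(paste("calibration standard did not reduce phase contrast at frame(s)",
               paste(calib_frames[per <= 0], collapse = ", "),
               "- check calibration frame flags"))
  structure(list(scale = mean(per), standard_concentration = concentration,
                 frames_used = calib_frames, per_frame = per),
            class = "calibration_scale")
}

#' @export
print.calibration_scale <- function(x, ...) {
  cat(sprintf("<calibration_scale> %.5g rad per mg/mL (standard %.0f mg/mL, %d frame(s))\n",
              x$scale, x$standard_concentration, length(x$frames_used)))
  invisible(x)
}

#' Build a calibration scale directly
#'
#' @param scale radians per mg/mL, > 0.
#' @param standard_concentration mg/mL.
#' @return `calibration_scale` object.
#' @export
calibration_scale <- function(scale, standard_concentration = NA_real_) {
  stopifnot(is.finite(scale), scale > 0)
  structure(list(scale = scale, standard_concentration = standard_concentration,
                 frames_used = integer(), per_frame = numeric()),
            class = "calibration_scale")
}

#' Convert phase to dry-mass density
#'
#' Per-pixel density is `phase / scale`; the cell density is the mean over the
#' mask pixels.
#'
#' @param map a background-corrected [phase_map()].
#' @param mask logical matrix (or `label_mask` plus `label`) selecting the
#'   cell's pixels.
#' @param scale a `calibration_scale`.
#' @param label cell label when `mask` is a `label_mask`.
#' @return list with `density` (mean over mask, mg/mL) and `density_map`
#'   (per-pixel matrix, mg/mL).
#' @export
phase_to_density <- function(map, mask, scale, label = NULL) {
  stopifnot(inherits(scale, "calibration_scale"))
  if (!map$background_corrected)
    qc_log("converting a phase map that is not background-corrected")
  if (inherits(mask, "label_mask")) {
    stopifnot(!is.null(label))
    mask <- unclass(mask) == label
  }
  if (!any(mask)) stop("empty cell mask")
  dmap <- map$phase / scale$scale
  list(density = mean(dmap[mask]), density_map = dmap)
}
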