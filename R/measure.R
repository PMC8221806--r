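# Bilinear interpolation of a matrix at physical coordinates (µm); pixel
# centers sit at (index - 0.5) * pixel_size (1-based indices).
interp2 <- function(m, x, y, pixel_size) {
  i <- y / pixel_size + 0.5
  j <- x / pixel_size + 0.5
  i <- pmin(pmax(i, 1), nrow(m)); j <- pmin(pmax(j, 1), ncol(m))
  i0 <- pmin(floor(i), nrow(m) - 1); j0 <- pmin(floor(j), ncol(m) - 1)
  fi <- i - i0; fj <- j - j0
  m[cbind(i0, j0)] * (1 - fi) * (1 - fj) + m[cbind(i0 + 1, j0)] * fi * (1 - fj) +
    m[cbind(i0, j0 + 1)] * (1 - fi) * fj + m[cbind(i0 + 1, j0 + 1)] * fi * fj
}

# Centerline coordinates of mask pixels: arclength s from tip A, perpendicular
# offset d, local section half-width r_loc and the rotational-symmetry chord
# (thickness) model t = 2 sqrt(r_loc^2 - d^2).
pixel_cell_coords <- function(mask, skeleton, pixel_size) {
  idx <- which(mask, arr.ind = TRUE)
  xpix <- (idx[, 2] - 0.5) * pixel_size
  ypix <- (idx[, 1] - 0.5) * pixel_size
  mid <- skeleton$mid
  nn <- vapply(seq_along(xpix), function(p) {
    which.min((mid[, 1] - xpix[p])^2 + (mid[, 2] - ypix[p])^2)
  }, 0L)
  tang <- tangent_at(skeleton)
  vx <- xpix - mid[nn, 1]; vy <- ypix - mid[nn, 2]
  along <- vx * tang[nn, 1] + vy * tang[nn, 2]
  s <- skeleton$s[nn] + along
  d <- sqrt(pmax(0, vx^2 + vy^2 - along^2))
  r_loc <- stats::approx(skeleton$s, skeleton$r, xout = s, rule = 2)$y
  # inside the caps the local half-width follows the cap sphere
  for (side in c("A", "B")) {
    dist_tip <- if (side == "A") s else skeleton$length - s
    cap_h <- skeleton$cap_extent[[side]]
    a <- if (side == "A") skeleton$r[1] else skeleton$r[length(skeleton$r)]
    in_cap <- dist_tip < cap_h + skeleton$spacing / 2
    if (any(in_cap) && cap_h > 0) {
      R <- (a^2 + cap_h^2) / (2 * cap_h)
      w <- sqrt(pmax(0, 2 * R * dist_tip[in_cap] - dist_tip[in_cap]^2))
      r_loc[in_cap] <- pmin(r_loc[in_cap], w)
    }
  }
  t_model <- 2 * sqrt(pmax(0, r_loc^2 - pmin(d, r_loc)^2))
  list(idx = idx, s = s, d = d, r_loc = r_loc, t_model = t_model)
}

#' Thickness-normalized per-pixel density map of one cell
#'
#' The raw per-pixel quantity `phase / scale` is proportional to the areal
#' (projected) dry mass, so thicker parts of the cell read denser. Assuming
#' rotational symmetry, each pixel's phase is divided by its modeled chord
#' length through the cell body (from the skeleton's section widths), making
#' the map an estimate of local volumetric density in mg/mL. Pixels whose
#' modeled chord is shorter than `min_chord` (thin edge and tip pixels, where
#' the normalization is ill-conditioned) are set to `NA`.
#'
#' @param map a background-corrected [phase_map()].
#' @param mask logical matrix of the cell's pixels.
#' @param skeleton the cell's skeleton.
#' @param scale a `calibration_scale`.
#' @param min_chord minimum modeled chord, µm.
#' @return matrix of local density (mg/mL), `NA` outside the usable cell
#'   area, with attribute `coords` (the pixel centerline coordinates).
#' @export
cell_density_map <- function(map, mask, skeleton, scale, min_chord = 0.5) {
  pc <- pixel_cell_coords(mask, skeleton, map$pixel_size)
  usable <- pc$t_model >= min_chord
  sel <- pc$idx[usable, , drop = FALSE]
  raw <- map$phase[sel] / pc$t_model[usable]
  # anchor the map's mean to the whole-cell mean density, which is unbiased
  # because the calibration ratio cancels the mean chord; the chord model
  # then only carries the *relative* (spatial) normalization
  rho_cell <- mean(map$phase[mask]) / scale$scale
  # anchor on well-conditioned central pixels; thin-edge pixels read low
  # (phase smoothing over a short chord) and would drag the factor down
  central <- pc$t_model[usable] >= 0.7 * max(pc$t_model)
  out <- matrix(NA_real_, nrow(map$phase), ncol(map$phase))
  out[sel] <- raw * rho_cell / mean(raw[central])
  attr(out, "coords") <- pc
  out
}

tangent_at <- function(sk) {
  m <- nrow(sk$mid)
  tg <- rbind(sk$mid[2, ] - sk$mid[1, ],
              sk$mid[3:m, , drop = FALSE] - sk$mid[1:(m - 2), , drop = FALSE],
              sk$mid[m, ] - sk$mid[m - 1, ])
  tl <- sqrt(rowSums(tg^2)); tl[tl == 0] <- 1
  tg / tl
}

#' Histogram-mode density of a polar region
#'
#' Returns the peak of the histogram (bin width 2 mg/mL, quadratic
#' interpolation of the top three bins) of density values within `depth` µm of
#' arclength distance from the chosen cell pole. The mode is robust to
#' high-density inclusions (droplets, septa) that would bias a mean.
#'
#' @param density_map per-pixel density, mg/mL (from [phase_to_density()]).
#' @param mask logical matrix of the cell's pixels.
#' @param skeleton the cell's [skeletonize_cell()] result.
#' @param pole `"A"` (tip at arclength 0) or `"B"`.
#' @param depth region depth from the pole tip, µm.
#' @param bin_width histogram bin width, mg/mL.
#' @param pixel_size µm.
#' @param min_pixels below this region size the mean is substituted (logged).
#' @return density, mg/mL.
#' @export
polar_density <- function(density_map, mask, skeleton, pole = c("A", "B"),
                          depth = 3, bin_width = 2, pixel_size, min_pixels = 50) {
  pole <- match.arg(pole)
  if (skeleton$length <= depth)
    stop("cell shorter than the polar region depth")
  pa <- pixel_cell_coords(mask, skeleton, pixel_size)
  dist_pole <- if (pole == "A") pa$s else skeleton$length - pa$s
  sel <- dist_pole <= depth
  vals <- density_map[pa$idx[sel, , drop = FALSE]]
  vals <- vals[is.finite(vals)]
  if (length(vals) < min_pixels) {
    qc_log("polar region has %d px (< %d); using mean", length(vals), min_pixels)
    return(mean(vals))
  }
  histogram_mode(vals, bin_width)
}

histogram_mode <- function(vals, bin_width) {
  lo <- floor(min(vals) / bin_width) * bin_width
  breaks <- seq(lo, max(vals) + bin_width, by = bin_width)
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  p <- which.max(h$counts)
  if (p == 1 || p == length(h$counts)) return(h$mids[p])
  c0 <- h$counts[p - 1]; c1 <- h$counts[p]; c2 <- h$counts[p + 1]
  den <- c0 - 2 * c1 + c2
  if (den == 0) return(h$mids[p])
  h$mids[p] + 0.5 * bin_width * (c0 - c2) / den
}

#' Septum position, bend direction and sagitta
#'
#' Detects a transverse high-density band (per-section mean density at least
#' `threshold_ratio` times the cell median, band width at most `max_band_um`),
#' traces the septum ridge as the maximal-density path across the cell width,
#' draws the chord between the ridge's contour junctions, and reports the
#' maximum perpendicular deviation (sagitta). Sagitta is signed positive when
#' the ridge bulges toward pole B; septa with |sagitta| below `flat_sagitta`
#' are reported as flat.
#'
#' @param density_map per-pixel density, mg/mL.
#' @param mask logical matrix of the cell's pixels.
#' @param skeleton the cell's skeleton.
#' @param pixel_size µm.
#' @param threshold_ratio band detection threshold relative to the cell
#'   median density.
#' @param max_band_um maximum band width, µm.
#' @param flat_sagitta below this |sagitta| (µm) the septum is called flat.
#' @return `NULL` when no band is detected; otherwise a list with `position`
#'   (fraction of cell length from pole A), `sagitta` (signed µm), `toward`
#'   (`"A"`, `"B"` or `"flat"`), `rho_A`, `rho_B` (compartment mean densities,
#'   mg/mL).
#' @export
measure_septum_bend <- function(density_map, mask, skeleton, pixel_size,
                                threshold_ratio = 1.3, max_band_um = 1,
                                flat_sagitta = 0.15) {
  sk <- skeleton
  m <- nrow(sk$mid)
  step <- pixel_size / 2
  med <- stats::median(density_map[mask], na.rm = TRUE)
  dmap <- density_map
  dmap[!is.finite(dmap)] <- med     # neutral fill for edge pixels
  # a bent band crosses each section only over part of the width, so a high
  # quantile of the transverse samples detects it where a mean would dilute
  secmean <- vapply(seq_len(m), function(i) {
    tt <- seq(-sk$r[i] * 0.85, sk$r[i] * 0.85, by = step)
    stats::quantile(interp2(dmap, sk$mid[i, 1] + tt * sk$dir[i, 1],
                            sk$mid[i, 2] + tt * sk$dir[i, 2], pixel_size),
                    0.9, names = FALSE)
  }, 0)
  hot <- secmean >= threshold_ratio * med
  if (!any(hot)) return(NULL)
  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cand <- which(runs$values & runs$lengths * sk$spacing <= max_band_um + sk$spacing / 2)
  if (!length(cand)) return(NULL)
  best <- cand[which.max(vapply(cand, function(ci) max(secmean[starts[ci]:ends[ci]]), 0))]
  band <- starts[best]:ends[best]
  i0 <- band[which.max(secmean[band])]
  s0 <- sum(sk$s[band] * secmean[band]) / sum(secmean[band])
  # ridge trace: at each transverse offset t, find the arclength s maximizing
  # density in a window around the band
  r0 <- sk$r[i0]
  tg <- tangent_at(sk)
  win <- which(abs(sk$s - s0) <= 0.75)
  if (length(win) < 3) win <- max(1, i0 - 3):min(m, i0 + 3)
  tvals <- seq(-r0 * 0.9, r0 * 0.9, by = step)
  ridge <- matrix(NA_real_, length(tvals), 2)
  ridge_s <- rep(NA_real_, length(tvals))
  for (j in seq_along(tvals)) {
    t <- tvals[j]
    xs <- sk$mid[win, 1] + t * sk$dir[win, 1]
    ys <- sk$mid[win, 2] + t * sk$dir[win, 2]
    dv <- interp2(dmap, xs, ys, pixel_size)
    p <- which.max(dv)
    sp <- sk$s[win][p]
    if (p > 1 && p < length(dv)) {
      den <- dv[p - 1] - 2 * dv[p] + dv[p + 1]
      if (den != 0)
        sp <- sp + 0.5 * sk$spacing * (dv[p - 1] - dv[p + 1]) / den
    }
    ridge_s[j] <- sp
    frac <- (sp - sk$s[win][1]) / max(diff(range(sk$s[win])), 1e-9)
    frac <- pmin(pmax(frac, 0), 1)
    k0 <- win[1] + frac * (length(win) - 1)
    kl <- floor(k0); kf <- k0 - kl
    kl <- min(max(kl, 1), m - 1)
    base <- (1 - kf) * sk$mid[kl, ] + kf * sk$mid[kl + 1, ]
    dirj <- (1 - kf) * sk$dir[kl, ] + kf * sk$dir[kl + 1, ]
    ridge[j, ] <- base + t * dirj / sqrt(sum(dirj^2))
  }
  ok <- is.finite(ridge_s)
  ridge <- ridge[ok, , drop = FALSE]; ridge_s <- ridge_s[ok]
  if (nrow(ridge) < 5) return(NULL)
  # chord between the contour junctions (ridge endpoints) and signed sagitta:
  # deviation measured along the local tangent (+ toward pole B)
  p1 <- ridge[1, ]; p2 <- ridge[nrow(ridge), ]
  chord <- p2 - p1; chord <- chord / sqrt(sum(chord^2))
  dev <- (ridge[, 1] - p1[1]) * (-chord[2]) + (ridge[, 2] - p1[2]) * chord[1]
  # orient the deviation axis toward increasing arclength (pole B)
  tg0 <- tg[i0, ]
  if (sum(c(-chord[2], chord[1]) * tg0) < 0) dev <- -dev
  sagitta <- dev[which.max(abs(dev))]
  toward <- if (abs(sagitta) < flat_sagitta) "flat" else if (sagitta > 0) "B" else "A"
  # compartment densities on each side of the ridge, excluding the band
  pa <- pixel_cell_coords(mask, skeleton, pixel_size)
  s_ridge <- mean(ridge_s)
  selA <- pa$s < s_ridge - max_band_um / 2
  selB <- pa$s > s_ridge + max_band_um / 2
  rho_A <- if (any(selA))
    mean(density_map[pa$idx[selA, , drop = FALSE]], na.rm = TRUE) else NA_real_
  rho_B <- if (any(selB))
    mean(density_map[pa$idx[selB, , drop = FALSE]], na.rm = TRUE) else NA_real_
  list(position = s0 / sk$length, sagitta = sagitta, toward = toward,
       rho_A = rho_A, rho_B = rho_B)
}

#' Measure one segmented cell
#'
#' Populates the full per-cell record: geometry from the skeleton, mean
#' density from the calibrated phase map, mass as `density * volume * 1e-3`
#' (pg = mg/mL x fL x 1e-3), polar densities from 3 µm pole regions, tip
#' positions, and (optionally) septum bend measurements.
#'
#' @param map a background-corrected [phase_map()].
#' @param mask a `label_mask`.
#' @param label cell label in the mask.
#' @param skeleton the cell's skeleton.
#' @param scale a `calibration_scale`.
#' @param frame frame id.
#' @param septum measure septum bend?
#' @param pole_depth polar region depth, µm.
#' @return one-row `data.frame` (a cell-measurement record).
#' @export
measure_cell <- function(map, mask, label, skeleton, scale, frame = 1L,
                         septum = FALSE, pole_depth = 3) {
  lm <- unclass(mask) == label
  if (!any(lm)) stop(sprintf("label %d absent from mask", label))
  px <- map$pixel_size
  pd <- phase_to_density(map, lm, scale)
  geo <- compute_geometry(skeleton)
  idx <- which(lm, arr.ind = TRUE)
  cx <- mean((idx[, 2] - 0.5) * px); cy <- mean((idx[, 1] - 0.5) * px)
  dnorm <- cell_density_map(map, lm, skeleton, scale)
  poleA <- tryCatch(polar_density(dnorm, lm, skeleton, "A",
                                  depth = pole_depth, pixel_size = px),
                    error = function(e) NA_real_)
  poleB <- tryCatch(polar_density(dnorm, lm, skeleton, "B",
                                  depth = pole_depth, pixel_size = px),
                    error = function(e) NA_real_)
  sep <- if (septum)
    measure_septum_bend(dnorm, lm, skeleton, px) else NULL
  data.frame(
    frame = frame, label = label,
    centroid_x = cx, centroid_y = cy,
    area_um2 = sum(lm) * px^2,
    length_um = geo$length, width_um = geo$mean_width,
    volume_fl = geo$volume, surface_area_um2 = geo$surface_area,
    density_mg_ml = pd$density,
    mass_pg = pd$density * geo$volume * 1e-3,
    pole_a_density = poleA, pole_b_density = poleB,
    tip_a_x = skeleton$tips[1, 1], tip_a_y = skeleton$tips[1, 2],
    tip_b_x = skeleton$tips[2, 1], tip_b_y = skeleton$tips[2, 2],
    bbox_xmin = min((idx[, 2] - 1) * px), bbox_xmax = max(idx[, 2] * px),
    bbox_ymin = min((idx[, 1] - 1) * px), bbox_ymax = max(idx[, 1] * px),
    septum_position = if (!is.null(sep)) sep$position else NA_real_,
    septum_sagitta = if (!is.null(sep)) sep$sagitta else NA_real_,
    septum_toward = if (!is.null(sep)) sep$toward else NA_character_,
    septum_rho_a = if (!is.null(sep)) sep$rho_A else NA_real_,
    septum_rho_b = if (!is.null(sep)) sep$rho_B else NA_real_,
    stringsAsFactors = FALSE)
}

#' Measure all cells in a frame
#'
#' Runs segmentation, contour extraction, skeletonization and per-cell
#' measurement on a calibrated phase map.
#'
#' @inheritParams measure_cell
#' @param min_area_um2 segmentation minimum area.
#' @return `data.frame` with one row per cell (possibly 0 rows).
#' @export
measure_frame <- function(map, scale, frame = 1L, min_area_um2 = 2,
                          septum = FALSE, pole_depth = 3) {
  mask <- segment_cells(map, min_area_um2 = min_area_um2, frame = frame)
  cts <- cell_contours(mask, map)
  rows <- list()
  for (ct in cts) {
    row <- tryCatch({
      sk <- skeletonize_cell(ct)
      measure_cell(map, mask, ct$label, sk, scale, frame = frame,
                   septum = septum, pole_depth = pole_depth)
    }, error = function(e) {
      qc_log("frame %d label %d failed: %s", frame, ct$label, conditionMessage(e))
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1]] <- row
  }
  if (!length(rows)) return(empty_measurements())
  do.call(rbind, rows)
}

empty_measurements <- function() {
  data.frame(frame = integer(), label = integer(), centroid_x = numeric(),
             centroid_y = numeric(), area_um2 = numeric(), length_um = numeric(),
             width_um = numeric(), volume_fl = numeric(),
             surface_area_um2 = numeric(), density_mg_ml = numeric(),
             mass_pg = numeric(), pole_a_density = numeric(),
             pole_b_density = numeric(), tip_a_x = numeric(), tip_a_y = numeric(),
             tip_b_x = numeric(), tip_b_y = numeric(), bbox_xmin = numeric(),
             bbox_xmax = numeric(), bbox_ymin = numeric(), bbox_ymax = numeric(),
             septum_position = numeric(), septum_sagitta = numeric(),
             septum_toward = character(), septum_rho_a = numeric(),
             septum_rho_b = numeric(), stringsAsFactors = FALSE)
}
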