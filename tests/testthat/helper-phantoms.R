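# Analytic contour builders and pipeline helpers shared across tests.

# Closed polygon of a spherocylinder outline (tip-to-tip length L, radius r).
sphero_contour <- function(L, r, angle = 0, center = c(0, 0), n_arc = 80,
                           n_side = 80) {
  hl <- L / 2 - r
  t1 <- seq(-pi / 2, pi / 2, length.out = n_arc)
  t2 <- seq(pi / 2, 3 * pi / 2, length.out = n_arc)
  xx <- c(seq(-hl, hl, length.out = n_side), hl + r * cos(t1),
          seq(hl, -hl, length.out = n_side), -hl + r * cos(t2))
  yy <- c(rep(-r, n_side), r * sin(t1), rep(r, n_side), r * sin(t2))
  a <- angle * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  m <- cbind(xx, yy) %*% t(R)
  cbind(m[, 1] + center[1], m[, 2] + center[2])
}

# Solid of revolution with hemispherical tips and a linear radius taper
# between them; returns the outline polygon and the exact volume/area by
# quadrature of the generating profile.
tapered_contour <- function(L, r0, r1, center = c(0, 0), n = 400) {
  # profile rr(s) over s in [0, L]: cap of radius r0, linear taper, cap r1
  rr <- function(s) {
    ifelse(s < r0, sqrt(pmax(0, 2 * r0 * s - s^2)),
           ifelse(s > L - r1, sqrt(pmax(0, 2 * r1 * (L - s) - (L - s)^2)),
                  r0 + (r1 - r0) * (s - r0) / (L - r0 - r1)))
  }
  s <- seq(0, L, length.out = n)
  top <- cbind(s - L / 2, rr(s))
  bot <- cbind(rev(s) - L / 2, -rr(rev(s)))
  xy <- rbind(top, bot)
  xy <- xy[c(TRUE, rowSums(abs(diff(xy))) > 1e-12), , drop = FALSE]
  vol <- stats::integrate(function(x) pi * rr(x)^2, 0, L,
                          subdivisions = 2000)$value
  list(xy = cbind(xy[, 1] + center[1], xy[, 2] + center[2]),
       volume = vol, profile = rr, length = L)
}

# Forward-simulate a phantom (with and without calibration standard),
# retrieve both phase maps, and return calibrated cell measurements.
calibrated_run <- function(spec, grid = phantom_grid(nx = 256, ny = 256),
                           mode = "angular", noise_sigma = 0, seed = 1L,
                           calib_conc = 100, septum = FALSE) {
  pm <- phase_from_density(spec, grid)
  st <- simulate_stack(pm, mode = mode, noise_sigma = noise_sigma, seed = seed)
  rec <- background_correct(retrieve_phase(select_planes(st)))
  pmc <- phase_from_density(spec, grid, medium_concentration = calib_conc)
  stc <- simulate_stack(pmc, mode = mode, noise_sigma = noise_sigma,
                        seed = seed + 1000L)
  recc <- background_correct(retrieve_phase(select_planes(stc)))
  mask <- segment_cells(rec)
  maskc <- segment_cells(recc)
  mp <- mean(rec$phase[unclass(mask) > 0])
  mpc <- mean(recc$phase[unclass(maskc) > 0])
  sc <- compute_calibration_scale(c(mp, mpc, mp), 2L, calib_conc)
  ms <- measure_frame(rec, sc, septum = septum)
  list(map = rec, mask = mask, scale = sc, measurements = ms)
}

# Measurement-like records straight from simulator ground truth (projected
# area and bounding box of the true spherocylinder), for lineage tests that
# should not depend on segmentation.
truth_records <- function(truth) {
  r <- truth$radius_um
  L <- truth$length_um
  data.frame(frame = truth$frame,
             label = truth$cell,
             centroid_x = truth$centroid_x, centroid_y = truth$centroid_y,
             area_um2 = 2 * r * (L - 2 * r) + pi * r^2,
             volume_fl = truth$volume_fl,
             density_mg_ml = truth$density_mg_ml,
             mass_pg = truth$mass_pg,
             bbox_xmin = pmin(truth$tip_old_x, truth$tip_new_x) - r,
             bbox_xmax = pmax(truth$tip_old_x, truth$tip_new_x) + r,
             bbox_ymin = pmin(truth$tip_old_y, truth$tip_new_y) - r,
             bbox_ymax = pmax(truth$tip_old_y, truth$tip_new_y) + r)
}
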