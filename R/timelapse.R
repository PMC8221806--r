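#' Time-lapse simulation settings
#'
#' Encodes the growth model used by the simulator: biomass is synthesized at
#' a constant relative rate throughout the cycle, volume grows by tip
#' elongation (old end faster than new end) during the growth phase, volume
#' growth halts during the division phase (septation), and at separation the
#' two daughters jointly swell by a fixed volume fraction at constant mass.
#' Defaults emulate fission yeast at 30 C: a 150 min cycle, ~4 µm old-end and
#' ~2 µm new-end elongation per cycle, a division phase occupying the last
#' quarter of the cycle, and a 5% separation swell.
#'
#' @param interval_min frame interval, min.
#' @param n_frames number of frames.
#' @param cycle_min cell-cycle duration, min.
#' @param mass_rate relative biomass synthesis rate per min; default
#'   `log(2) / cycle_min` (mass doubles over one cycle).
#' @param old_end_rate,new_end_rate tip elongation rates, µm/min, active
#'   during the growth phase.
#' @param division_fraction fraction of the cycle (at its end) with volume
#'   growth halted; in `[0, 1)`.
#' @param swell_fraction joint daughter volume inflation at separation.
#' @param separation_gap visible gap opened between daughters at separation,
#'   µm.
#' @param septum_ratio septum band density relative to the body density.
#' @param septum_thickness_um septum band thickness, µm.
#' @param calib_frames frame indices imaged with the calibration standard in
#'   the medium.
#' @param calib_concentration standard concentration, mg/mL.
#' @param noise_sigma camera noise SD as a fraction of background intensity.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return object of class `timelapse_spec`.
#' @export
timelapse_spec <- function(interval_min = 5, n_frames = 30, cycle_min = 150,
                           mass_rate = log(2) / cycle_min,
                           old_end_rate = 0.035, new_end_rate = 0.018,
                           division_fraction = 0.25, swell_fraction = 0.05,
                           separation_gap = 0.25, septum_ratio = 1.5,
                           septum_thickness_um = 0.3,
                           calib_frames = integer(),
                           calib_concentration = 100,
                           noise_sigma = 0, seed = 1L) {
  stopifnot(division_fraction >= 0, division_fraction < 1,
            swell_fraction >= 0, interval_min > 0, n_frames >= 1)
  structure(list(interval_min = interval_min, n_frames = n_frames,
                 cycle_min = cycle_min, mass_rate = mass_rate,
                 old_end_rate = old_end_rate, new_end_rate = new_end_rate,
                 division_fraction = division_fraction,
                 swell_fraction = swell_fraction,
                 separation_gap = separation_gap,
                 septum_ratio = septum_ratio,
                 septum_thickness_um = septum_thickness_um,
                 calib_frames = as.integer(calib_frames),
                 calib_concentration = calib_concentration,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "timelapse_spec")
}

#' Seed cell for a time-lapse simulation
#'
#' @param center cell center (x, y), µm.
#' @param length tip-to-tip length, µm.
#' @param angle axis angle in the plane, degrees; the old end sits at
#'   `center - (length/2) * u`.
#' @param radius µm.
#' @param density initial dry-mass density, mg/mL (sets the initial mass).
#' @param age initial cycle age, min.
#' @param axial_gradient mg/mL per µm along old -> new.
#' @return list describing the cell state.
#' @export
seed_cell <- function(center, length = 8, angle = 0, radius = 1.9,
                      density = 270, age = 0, axial_gradient = 0) {
  a <- angle * pi / 180
  u <- c(cos(a), sin(a))
  V <- sphero_volume(length, radius)
  list(p_old = center - (length / 2) * u, p_new = center + (length / 2) * u,
       radius = radius, mass = density * V * 1e-3, age = age,
       axial_gradient = axial_gradient)
}

sphero_volume <- function(L, r) pi * r^2 * L - (2 / 3) * pi * r^3

# Minimum distance between two segments p1-q1 and p2-q2 (2-D).
seg_seg_dist <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1^2); e <- sum(d2^2); f <- sum(d2 * r)
  if (a == 0 && e == 0) return(sqrt(sum(r^2)))
  if (a == 0) { s <- 0; t <- min(max(f / e, 0), 1) }
  else {
    c_ <- sum(d1 * r)
    if (e == 0) { t <- 0; s <- min(max(-c_ / a, 0), 1) }
    else {
      b <- sum(d1 * d2)
      den <- a * e - b^2
      s <- if (den != 0) min(max((b * f - c_ * e) / den, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-c_ / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - c_) / a, 0), 1) }
    }
  }
  sqrt(sum((p1 + s * d1 - (p2 + t * d2))^2))
}

cell_axis <- function(cell) {
  u <- cell$p_new - cell$p_old
  L <- sqrt(sum(u^2)); u <- u / L
  list(a = cell$p_old + cell$radius * u, b = cell$p_new - cell$radius * u)
}

# Push overlapping cells apart (cells in a chamber displace each other as
# they elongate); a few relaxation sweeps are enough for chain layouts.
resolve_contacts <- function(cells, gap, sweeps = 5) {
  n <- length(cells)
  if (n < 2) return(cells)
  for (sw in seq_len(sweeps)) {
    moved <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ai <- cell_axis(cells[[i]]); aj <- cell_axis(cells[[j]])
      d <- seg_seg_dist(ai$a, ai$b, aj$a, aj$b)
      need <- cells[[i]]$radius + cells[[j]]$radius + gap
      if (d < need - 1e-9) {
        ci <- (cells[[i]]$p_old + cells[[i]]$p_new) / 2
        cj <- (cells[[j]]$p_old + cells[[j]]$p_new) / 2
        dir <- cj - ci
        nd <- sqrt(sum(dir^2))
        dir <- if (nd > 1e-9) dir / nd else c(1, 0)
        shift <- (need - d) / 2 * dir
        cells[[i]]$p_old <- cells[[i]]$p_old - shift
        cells[[i]]$p_new <- cells[[i]]$p_new - shift
        cells[[j]]$p_old <- cells[[j]]$p_old + shift
        cells[[j]]$p_new <- cells[[j]]$p_new + shift
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  cells
}

cell_state_spec <- function(cell, tl, in_division, medium = 0) {
  L <- sqrt(sum((cell$p_new - cell$p_old)^2))
  u <- (cell$p_new - cell$p_old) / L
  V <- sphero_volume(L, cell$radius)
  septa <- list()
  rho_b <- cell$mass * 1e3 / V
  if (in_division) {
    V_sep <- pi * cell$radius^2 * tl$septum_thickness_um
    rho_b <- cell$mass * 1e3 / (V + (tl$septum_ratio - 1) * V_sep)
    septa <- list(c(0.5, tl$septum_thickness_um, tl$septum_ratio * rho_b))
  }
  phantom_spec(length = L, radius = cell$radius,
               angle = atan2(u[2], u[1]) * 180 / pi,
               center = (cell$p_old + cell$p_new) / 2,
               base_density = rho_b, axial_gradient = cell$axial_gradient,
               septa = septa, medium_concentration = medium)
}

#' Simulate a bright-field time-lapse with ground truth
#'
#' Steps a population of rod-shaped cells through growth, septation,
#' separation (with swell) and division; renders each frame's phase map (and
#' optionally a defocus stack) and emits a ground-truth table with one row
#' per cell per frame.
#'
#' @param tl a [timelapse_spec()].
#' @param cells list of [seed_cell()] states.
#' @param grid a [phantom_grid()].
#' @param render `"phase"` (phase maps only), `"stack"` (defocus stacks via
#'   [simulate_stack()]), or `"none"` (ground truth only).
#' @param wavelength µm.
#' @param z_offsets stack offsets, µm (render = "stack").
#' @param mode forward model for stacks.
#' @return list with `frames` (per frame: `phase` and optionally `stack`),
#'   `truth` (data.frame), `tl`, `grid`.
#' @export
simulate_timelapse <- function(tl, cells, grid = phantom_grid(),
                               render = c("phase", "stack", "none"),
                               wavelength = 0.68,
                               z_offsets = c(-1.5, -1, -0.5, 0, 0.5, 1, 1.5),
                               mode = "angular") {
  render <- match.arg(render)
  stopifnot(inherits(tl, "timelapse_spec"))
  for (i in seq_along(cells)) {
    cells[[i]]$id <- i
    cells[[i]]$parent <- NA_integer_
    cells[[i]]$born <- FALSE
  }
  next_id <- length(cells) + 1L
  dt <- tl$interval_min
  growth_span <- (1 - tl$division_fraction) * tl$cycle_min
  truth <- list()
  frames <- vector("list", tl$n_frames)
  for (f in seq_len(tl$n_frames)) {
    t_min <- (f - 1) * dt
    if (f > 1) {
      stepped <- list()
      for (cell in cells) {
        cell$born <- FALSE
        u <- (cell$p_new - cell$p_old)
        u <- u / sqrt(sum(u^2))
        grow_t <- max(0, min(cell$age + dt, growth_span) - cell$age)
        cell$p_old <- cell$p_old - u * tl$old_end_rate * grow_t
        cell$p_new <- cell$p_new + u * tl$new_end_rate * grow_t
        cell$mass <- cell$mass * exp(tl$mass_rate * dt)
        cell$age <- cell$age + dt
        if (cell$age >= tl$cycle_min) {
          # separation: split at the septum mid-point, joint swell at
          # constant total mass
          L <- sqrt(sum((cell$p_new - cell$p_old)^2))
          m <- (cell$p_old + cell$p_new) / 2
          V_m <- sphero_volume(L, cell$radius)
          # solve sum of two daughter spherocylinder volumes =
          # (1 + swell) * V_m for the common daughter length
          L_d <- ((1 + tl$swell_fraction) * V_m + (4 / 3) * pi * cell$radius^3) /
            (2 * pi * cell$radius^2)
          g2 <- tl$separation_gap / 2
          dA <- cell; dB <- cell
          # daughter A inherits the mother's old tip side; daughter B's old
          # end is the mother's new tip; both new ends face the septum
          dA$p_old <- m - (g2 + L_d) * u; dA$p_new <- m - g2 * u
          dB$p_old <- m + (g2 + L_d) * u; dB$p_new <- m + g2 * u
          dA$mass <- cell$mass / 2; dB$mass <- cell$mass / 2
          dA$age <- cell$age - tl$cycle_min; dB$age <- dA$age
          dA$parent <- cell$id; dB$parent <- cell$id
          dA$id <- next_id; dB$id <- next_id + 1L
          next_id <- next_id + 2L
          dA$born <- TRUE; dB$born <- TRUE
          dA$axial_gradient <- cell$axial_gradient
          dB$axial_gradient <- -cell$axial_gradient
          stepped[[length(stepped) + 1]] <- dA
          stepped[[length(stepped) + 1]] <- dB
        } else {
          stepped[[length(stepped) + 1]] <- cell
        }
      }
      cells <- resolve_contacts(stepped, tl$separation_gap)
    }
    is_calib <- f %in% tl$calib_frames
    medium <- if (is_calib) tl$calib_concentration else 0
    specs <- vector("list", length(cells))
    for (i in seq_along(cells)) {
      cell <- cells[[i]]
      in_div <- cell$age >= growth_span
      specs[[i]] <- tryCatch(
        cell_state_spec(cell, tl, in_div, medium),
        error = function(e)
          stop(sprintf("frame %d, cell %d: %s (cell grew out of the field?)",
                       f, cell$id, conditionMessage(e))))
      L <- specs[[i]]$length
      V <- sphero_volume(L, cell$radius)
      truth[[length(truth) + 1]] <- data.frame(
        frame = f, time_min = t_min, cell = cell$id, parent = cell$parent,
        length_um = L, radius_um = cell$radius, volume_fl = V,
        mass_pg = cell$mass, density_mg_ml = cell$mass * 1e3 / V,
        tip_old_x = cell$p_old[1], tip_old_y = cell$p_old[2],
        tip_new_x = cell$p_new[1], tip_new_y = cell$p_new[2],
        centroid_x = (cell$p_old[1] + cell$p_new[1]) / 2,
        centroid_y = (cell$p_old[2] + cell$p_new[2]) / 2,
        age_min = cell$age,
        phase = if (in_div) "division" else "growth",
        separation = cell$born, calibration = is_calib,
        stringsAsFactors = FALSE)
    }
    if (render != "none") {
      areal <- matrix(0, grid$ny, grid$nx)
      thick <- matrix(0, grid$ny, grid$nx)
      for (sp in specs) {
        pr <- project_phantom(sp, grid)
        areal <- areal + pr$areal
        thick <- thick + pr$thickness
      }
      phi <- (2 * pi / wavelength) * 0.18 * 1e-3 * (areal - medium * thick)
      pmap <- phase_map(phi, grid$pixel_size)
      fr <- list(phase = pmap)
      if (render == "stack")
        fr$stack <- simulate_stack(pmap, z_offsets, wavelength,
                                   noise_sigma = tl$noise_sigma,
                                   seed = tl$seed + f, mode = mode)
      frames[[f]] <- fr
    }
  }
  list(frames = frames, truth = do.call(rbind, truth), tl = tl, grid = grid)
}
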