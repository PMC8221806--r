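#' Spherocylindrical cell phantom
#'
#' Describes a rod-shaped cell as a cylinder of length `length - 2*radius`
#' capped by two hemispheres, carrying a dry-mass density field: a uniform
#' base density, an optional linear axial gradient (signed along the old-end
#' to new-end axis), optional septa (transverse high-density bands) and
#' optional spherical high-density droplets.
#'
#' @param length tip-to-tip cell length, µm; must exceed `2 * radius`.
#' @param radius cell radius, µm.
#' @param angle centerline angle in the image plane, degrees; the old end sits
#'   at `center - (length/2) * (cos a, sin a)`.
#' @param center cell mid-point `(x, y)`, µm.
#' @param base_density dry-mass density at the cell mid-point, mg/mL.
#' @param axial_gradient mg/mL per µm, applied along the old-to-new axis.
#' @param septa list of `c(position, thickness, density)`: axial position as a
#'   fraction of the length (0 = old tip), band thickness µm, density mg/mL.
#' @param droplets list of `c(x, y, radius, density)`: droplet center µm
#'   (mid-plane), radius µm, density mg/mL. Droplets must lie inside the body.
#' @param medium_concentration dry-mass concentration of the surrounding
#'   medium, mg/mL (nonzero only at calibration-standard timepoints).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(length, radius, angle = 0, center = c(0, 0),
                         base_density = 282, axial_gradient = 0,
                         septa = list(), droplets = list(),
                         medium_concentration = 0) {
  stopifnot(length > 2 * radius, radius > 0, base_density >= 0)
  dens_at_tips <- base_density + c(-1, 1) * axial_gradient * length / 2
  if (any(dens_at_tips < 0))
    stop("axial gradient drives density negative at a cell tip")
  for (d in droplets) {
    dd <- sqrt(sum((d[1:2] - center)^2))
    # conservative containment check along the axis
    a <- angle * pi / 180
    u <- c(cos(a), sin(a))
    half <- c(center - (length / 2 - radius) * u, center + (length / 2 - radius) * u)
    dist <- dist_to_segment(d[1], d[2], half[1:2], half[3:4])
    if (dist + d[3] > radius)
      stop("droplet extends outside the cell body")
  }
  structure(list(length = length, radius = radius, angle = angle,
                 center = center, base_density = base_density,
                 axial_gradient = axial_gradient, septa = septa,
                 droplets = droplets,
                 medium_concentration = medium_concentration),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> L=%.2f um, r=%.2f um, angle=%.1f deg, rho=%.1f mg/mL\n",
              x$length, x$radius, x$angle, x$base_density))
  if (x$axial_gradient != 0)
    cat(sprintf("  axial gradient %.2f mg/mL/um\n", x$axial_gradient))
  if (length(x$septa)) cat(sprintf("  %d septum band(s)\n", length(x$septa)))
  if (length(x$droplets)) cat(sprintf("  %d droplet(s)\n", length(x$droplets)))
  invisible(x)
}

#' Voxel/pixel grid geometry
#'
#' @param nx,ny in-plane grid size, pixels.
#' @param pixel_size in-plane voxel size, µm (isotropic in-plane).
#' @param nz number of z-planes for volumetric rendering.
#' @param z_step z voxel size, µm.
#' @param origin physical position of the (0, 0) pixel corner, µm.
#' @return A `phantom_grid` list.
#' @export
phantom_grid <- function(nx = 256, ny = 256, pixel_size = 0.1075,
                         nz = 49, z_step = 0.1, origin = c(0, 0)) {
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 pixel_size = pixel_size, nz = as.integer(nz),
                 z_step = z_step, origin = origin),
            class = "phantom_grid")
}

grid_coords <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$nx) - 0.5) * grid$pixel_size,
       y = grid$origin[2] + (seq_len(grid$ny) - 0.5) * grid$pixel_size,
       z = (seq_len(grid$nz) - (grid$nz + 1) / 2) * grid$z_step)
}

phantom_tips <- function(spec) {
  a <- spec$angle * pi / 180
  u <- c(cos(a), sin(a))
  list(u = u,
       old = spec$center - (spec$length / 2) * u,
       new = spec$center + (spec$length / 2) * u,
       axis_a = spec$center - (spec$length / 2 - spec$radius) * u,
       axis_b = spec$center + (spec$length / 2 - spec$radius) * u)
}

# Axial density profile: density as a function of arclength s from the old
# tip (vectorised). Septa bands replace the local density.
axial_density <- function(spec, s) {
  rho <- spec$base_density + spec$axial_gradient * (s - spec$length / 2)
  for (sp in spec$septa) {
    inside <- abs(s - sp[1] * spec$length) <= sp[2] / 2
    rho[inside] <- sp[3]
  }
  rho
}

check_grid_bounds <- function(spec, grid, margin = 0.5, check_z = TRUE) {
  co <- grid_coords(grid)
  t <- phantom_tips(spec)
  ext <- spec$radius + margin
  lo <- pmin(t$axis_a, t$axis_b) - ext
  hi <- pmax(t$axis_a, t$axis_b) + ext
  if (lo[1] < min(co$x) - grid$pixel_size / 2 || hi[1] > max(co$x) + grid$pixel_size / 2 ||
      lo[2] < min(co$y) - grid$pixel_size / 2 || hi[2] > max(co$y) + grid$pixel_size / 2)
    stop(sprintf(paste0("phantom (x: %.2f..%.2f, y: %.2f..%.2f um, incl. %.1f um margin) ",
                        "exceeds grid (x: 0..%.2f, y: 0..%.2f um)"),
                 lo[1], hi[1], lo[2], hi[2], margin,
                 grid$nx * grid$pixel_size, grid$ny * grid$pixel_size))
  if (check_z && !is.null(grid$nz) && grid$nz * grid$z_step < 2 * ext)
    stop("z extent of grid too small for phantom radius plus margin")
  invisible(TRUE)
}

#' Render a phantom to a voxel density volume
#'
#' Rasterizes the spherocylinder onto a 3-D voxel grid with anti-aliased
#' partial-volume boundary voxels: a voxel whose center lies within half a
#' voxel of the surface gets a linearly interpolated occupancy fraction.
#' Returned voxel values are density times occupancy, so the mass integral
#' `sum(vol) * voxel_volume * 1e-3` (pg) matches the analytic phantom mass.
#'
#' @param spec a [phantom_spec()].
#' @param grid a [phantom_grid()]; must enclose the phantom with >= 0.5 µm
#'   margin.
#' @return A 3-D array `[y, x, z]` of density (mg/mL), class `density_volume`,
#'   with attributes `pixel_size`, `z_step`, `origin` and `occupancy` (the
#'   occupancy-fraction array, used for path-length computations).
#' @export
render_phantom <- function(spec, grid) {
  check_grid_bounds(spec, grid)
  co <- grid_coords(grid)
  t <- phantom_tips(spec)
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  px <- rep(co$x, each = ny)
  py <- rep(co$y, times = nx)
  # in-plane distance to axis segment and axial coordinate
  vx <- t$axis_b[1] - t$axis_a[1]; vy <- t$axis_b[2] - t$axis_a[2]
  L2 <- vx^2 + vy^2
  tt <- pmin(1, pmax(0, ((px - t$axis_a[1]) * vx + (py - t$axis_a[2]) * vy) / L2))
  d2xy <- (px - t$axis_a[1] - tt * vx)^2 + (py - t$axis_a[2] - tt * vy)^2
  # axial arclength from the old tip (unclamped projection + cap radius)
  s_axis <- ((px - t$axis_a[1]) * vx + (py - t$axis_a[2]) * vy) / sqrt(L2) + spec$radius
  rho_ax <- axial_density(spec, pmin(spec$length, pmax(0, s_axis)))
  h <- grid$pixel_size
  vol <- array(0, dim = c(ny, nx, nz))
  occ <- array(0, dim = c(ny, nx, nz))
  for (k in seq_len(nz)) {
    dz2 <- co$z[k]^2
    sd <- sqrt(d2xy + dz2) - spec$radius
    ok <- pmin(1, pmax(0, 0.5 - sd / h))
    rho <- rho_ax
    for (dr in spec$droplets) {
      din <- sqrt((px - dr[1])^2 + (py - dr[2])^2 + dz2) - dr[3]
      f <- pmin(1, pmax(0, 0.5 - din / h))
      rho <- rho * (1 - f) + dr[4] * f
    }
    occ[, , k] <- ok
    vol[, , k] <- rho * ok
  }
  structure(vol, pixel_size = grid$pixel_size, z_step = grid$z_step,
            origin = grid$origin, occupancy = occ, class = "density_volume")
}

#' Analytic projection of a phantom to areal density
#'
#' Computes the z-integral of the phantom's density field in closed form:
#' the chord length through a spherocylinder at in-plane distance `d` from the
#' axis segment is `2 * sqrt(r^2 - d^2)` everywhere (cylinder and caps alike),
#' and the axial density is constant along each vertical chord. Used by the
#' time-lapse simulator where full voxel rendering would be wasteful.
#'
#' @inheritParams render_phantom
#' @return list with matrices `areal` ((mg/mL)·µm), `thickness` (µm) and
#'   `area_px` (projected in-plane occupancy fraction per pixel).
#' @export
project_phantom <- function(spec, grid) {
  g2 <- structure(list(nx = grid$nx, ny = grid$ny, pixel_size = grid$pixel_size,
                       nz = 1L, z_step = 1, origin = grid$origin),
                  class = "phantom_grid")
  check_grid_bounds(spec, g2, check_z = FALSE)
  co <- grid_coords(g2)
  t <- phantom_tips(spec)
  nx <- grid$nx; ny <- grid$ny
  px <- rep(co$x, each = ny)
  py <- rep(co$y, times = nx)
  vx <- t$axis_b[1] - t$axis_a[1]; vy <- t$axis_b[2] - t$axis_a[2]
  L2 <- vx^2 + vy^2
  tt <- pmin(1, pmax(0, ((px - t$axis_a[1]) * vx + (py - t$axis_a[2]) * vy) / L2))
  d <- sqrt((px - t$axis_a[1] - tt * vx)^2 + (py - t$axis_a[2] - tt * vy)^2)
  s_axis <- ((px - t$axis_a[1]) * vx + (py - t$axis_a[2]) * vy) / sqrt(L2) + spec$radius
  rho <- axial_density(spec, pmin(spec$length, pmax(0, s_axis)))
  r <- spec$radius
  thick <- ifelse(d < r, 2 * sqrt(pmax(0, r^2 - d^2)), 0)
  # in-plane anti-aliasing of the projected footprint
  h <- grid$pixel_size
  frac <- pmin(1, pmax(0, 0.5 - (d - r) / h))
  areal <- rho * thick
  for (dr in spec$droplets) {
    dd <- sqrt((px - dr[1])^2 + (py - dr[2])^2)
    chord <- ifelse(dd < dr[3], 2 * sqrt(pmax(0, dr[3]^2 - dd^2)), 0)
    areal <- areal + (dr[4] - rho) * chord
  }
  list(areal = matrix(areal, ny, nx), thickness = matrix(thick, ny, nx),
       area_px = matrix(frac, ny, nx))
}

#' Closed-form phantom volume, area and mass
#'
#' Volume `pi r^2 (L - 2r) + 4/3 pi r^3`, surface `2 pi r (L - 2r) + 4 pi r^2`,
#' and mass as the density integral: a symmetric axial gradient integrates to
#' zero, septa add `(rho_s - rho_local) * pi r_s^2 * thickness` per band, and
#' droplets add `(rho_d - rho_local) * 4/3 pi r_d^3`.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (fL), `surface_area` (µm²), `mass` (pg),
#'   `mean_density` (mg/mL).
#' @export
phantom_truth <- function(spec) {
  L <- spec$length; r <- spec$radius
  V <- pi * r^2 * (L - 2 * r) + 4 / 3 * pi * r^3
  A <- 2 * pi * r * (L - 2 * r) + 4 * pi * r^2
  # gradient contribution: integral of g*(s - L/2) over the solid; compute the
  # first moment of cross-sectional area about mid-length (zero by symmetry).
  mass <- spec$base_density * V
  for (sp in spec$septa) {
    s0 <- sp[1] * L
    # cross-section radius at the band (caps taper)
    dist_tip <- min(s0, L - s0)
    rs <- if (dist_tip >= r) r else sqrt(pmax(0, r^2 - (r - dist_tip)^2))
    local <- spec$base_density + spec$axial_gradient * (s0 - L / 2)
    mass <- mass + (sp[3] - local) * pi * rs^2 * sp[2]
  }
  for (dr in spec$droplets) {
    t <- phantom_tips(spec)
    s0 <- sum((dr[1:2] - t$old) * t$u)
    local <- spec$base_density + spec$axial_gradient * (s0 - L / 2)
    mass <- mass + (dr[4] - local) * 4 / 3 * pi * dr[3]^3
  }
  list(volume = V, surface_area = A, mass = mass * 1e-3,
       mean_density = mass / V)
}

#' Integrated mass of a rendered density volume
#'
#' @param vol a `density_volume`.
#' @return mass in pg (`sum(density) * voxel_volume * 1e-3`).
#' @export
volume_mass <- function(vol) {
  vx <- attr(vol, "pixel_size")^2 * attr(vol, "z_step")
  sum(vol) * vx * 1e-3
}
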