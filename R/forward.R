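#' Phase map container
#'
#' @param phase 2-D matrix of phase shifts, radians.
#' @param pixel_size pixel size, µm.
#' @param background_corrected logical flag.
#' @param provenance optional identifier of the source stack.
#' @return object of class `phase_map`.
#' @export
phase_map <- function(phase, pixel_size, background_corrected = FALSE,
                      provenance = NULL) {
  stopifnot(is.matrix(phase), all(is.finite(phase)), pixel_size > 0)
  structure(list(phase = phase, pixel_size = pixel_size,
                 background_corrected = background_corrected,
                 provenance = provenance),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %d x %d px @ %.4f um, range [%.3f, %.3f] rad%s\n",
              nrow(x$phase), ncol(x$phase), x$pixel_size,
              min(x$phase), max(x$phase),
              if (x$background_corrected) ", background-corrected" else ""))
  invisible(x)
}

#' Bright-field z-stack container
#'
#' @param intensity 3-D array `[y, x, plane]`, arbitrary camera units, >= 0.
#' @param z_positions plane offsets relative to focus, µm, strictly increasing.
#' @param pixel_size pixel size, µm.
#' @param wavelength illumination wavelength, µm.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(intensity, z_positions, pixel_size, wavelength) {
  stopifnot(length(dim(intensity)) == 3,
            dim(intensity)[3] == length(z_positions),
            length(z_positions) >= 3,
            all(diff(z_positions) > 0),
            all(is.finite(intensity)),
            pixel_size > 0, wavelength > 0)
  if (any(intensity < 0))
    qc_log("image stack contains negative intensities (linearized forward model?)")
  structure(list(intensity = intensity, z_positions = z_positions,
                 pixel_size = pixel_size, wavelength = wavelength),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d x %d px, %d planes (z %s um) @ %.4f um, lambda %.3f um\n",
              dim(x$intensity)[1], dim(x$intensity)[2], dim(x$intensity)[3],
              paste(signif(range(x$z_positions), 3), collapse = ".."),
              x$pixel_size, x$wavelength))
  invisible(x)
}

#' Phase shift of a phantom or density volume
#'
#' Projects dry-mass density to optical phase:
#' `phi(x, y) = (2 pi / lambda) * alpha * integral of rho dz`, with density in
#' g/mL (mg/mL values are scaled by 1e-3). When the medium carries a
#' calibration standard (`medium_concentration` > 0 in the phantom), the
#' medium concentration is subtracted over the cell path length, reducing the
#' cell's phase contrast exactly as dissolved standard does in the instrument.
#'
#' @param x a `density_volume` from [render_phantom()], or a `phantom_spec`
#'   (projected analytically via [project_phantom()]).
#' @param grid a [phantom_grid()]; required when `x` is a `phantom_spec`.
#' @param wavelength illumination wavelength, µm.
#' @param refractive_increment specific refractive increment alpha, mL/g
#'   (~0.18 for protein).
#' @param medium_concentration overrides the phantom's medium concentration
#'   (mg/mL) when not `NULL`.
#' @return a [phase_map()].
#' @export
phase_from_density <- function(x, grid = NULL, wavelength = 0.68,
                               refractive_increment = 0.18,
                               medium_concentration = NULL) {
  stopifnot(wavelength > 0)
  if (inherits(x, "phantom_spec")) {
    stopifnot(!is.null(grid))
    pr <- project_phantom(x, grid)
    med <- if (is.null(medium_concentration)) x$medium_concentration else medium_concentration
    areal <- pr$areal - med * pr$thickness
    px <- grid$pixel_size
  } else if (inherits(x, "density_volume")) {
    zs <- attr(x, "z_step")
    areal <- apply(unclass(x), c(1, 2), sum) * zs
    med <- if (is.null(medium_concentration)) 0 else medium_concentration
    if (med != 0) {
      thick <- apply(attr(x, "occupancy"), c(1, 2), sum) * zs
      areal <- areal - med * thick
    }
    px <- attr(x, "pixel_size")
  } else stop("x must be a phantom_spec or density_volume")
  phi <- (2 * pi / wavelength) * refractive_increment * 1e-3 * areal
  phase_map(phi, px)
}

#' Forward-simulate a defocus z-stack from a phase map
#'
#' Treats the specimen as a pure-phase object under coherent plane-wave
#' illumination: the exit field `exp(i phi)` is propagated to each defocus
#' offset. Two forward models are provided:
#' \describe{
#'   \item{`"angular"`}{angular-spectrum (nonparaxial) defocus of the full
#'     complex field; contrast is nonlinear in phi, so the inverse solver is
#'     exercised against a model it does not trivially invert.}
#'   \item{`"linear"`}{the linearized transport-of-intensity forward map
#'     `I(z) = bg * (1 - (z/k) * laplacian(phi))`, the regime in which the
#'     inverse problem is exactly posed; used for unit-level consistency
#'     checks.}
#' }
#' Gaussian noise (sigma expressed as a fraction of the background level) is
#' added with a fixed seed for reproducibility.
#'
#' @param phase a [phase_map()].
#' @param z_offsets defocus offsets, µm; must be symmetric about 0 and
#'   include 0.
#' @param wavelength µm.
#' @param noise_sigma Gaussian noise SD as a fraction of background.
#' @param seed integer RNG seed (only used when `noise_sigma > 0`).
#' @param mode `"angular"` or `"linear"`.
#' @param background uniform background intensity level.
#' @param pad mirror-padding width in pixels for the propagation FFTs.
#' @return an [image_stack()].
#' @export
simulate_stack <- function(phase, z_offsets = c(-1.5, -1, -0.5, 0, 0.5, 1, 1.5),
                           wavelength = 0.68, noise_sigma = 0, seed = NULL,
                           mode = c("angular", "linear"), background = 1,
                           pad = 32) {
  mode <- match.arg(mode)
  z_offsets <- sort(z_offsets)
  if (max(abs(z_offsets + rev(z_offsets))) > 1e-9 || !any(z_offsets == 0))
    stop("z_offsets must be symmetric about 0 and include 0")
  phi <- mirror_pad(phase$phase, pad)
  nr <- nrow(phi); nc <- ncol(phi)
  qx <- fft_freq(nc, phase$pixel_size)
  qy <- fft_freq(nr, phase$pixel_size)
  q2 <- outer(qy^2, qx^2, `+`)
  k <- 2 * pi / wavelength
  if (max(sqrt(q2)) > 2 * k)
    qc_log("propagation grid samples frequencies beyond 2k; offsets near grid validity limit")
  planes <- array(0, dim = c(nrow(phase$phase), ncol(phase$phase), length(z_offsets)))
  if (mode == "angular") {
    U <- stats::fft(exp(1i * phi))
    kz <- sqrt(as.complex(k^2 - q2))   # Im(kz) >= 0 on the principal branch
    for (j in seq_along(z_offsets)) {
      z <- z_offsets[j]
      H <- exp(1i * z * Re(kz) - abs(z) * Im(kz))
      u <- stats::fft(U * H, inverse = TRUE) / (nr * nc)
      I <- Mod(u)^2 * background
      planes[, , j] <- crop_pad(I, pad, nrow(phase$phase), ncol(phase$phase))
    }
  } else {
    lap <- Re(stats::fft(stats::fft(phi) * (-q2), inverse = TRUE)) / (nr * nc)
    lap <- crop_pad(lap, pad, nrow(phase$phase), ncol(phase$phase))
    for (j in seq_along(z_offsets))
      planes[, , j] <- background * (1 - (z_offsets[j] / k) * lap)
  }
  if (noise_sigma > 0) {
    noise <- with_seed(seed, stats::rnorm(length(planes), 0, noise_sigma * background))
    planes <- planes + array(noise, dim = dim(planes))
  }
  if (mode == "angular") {
    planes[planes < 0] <- 0
  } else if (any(planes < 0)) {
    # the linearized map can undershoot zero at strong-phase edges; the values
    # are kept so the model remains exactly invertible by the TIE solver
    qc_log("linearized forward model produced %d negative-intensity pixels",
           sum(planes < 0))
  }
  image_stack(planes, z_offsets, phase$pixel_size, wavelength)
}
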