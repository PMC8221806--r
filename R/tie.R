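#' Find the focal plane of a bright-field stack
#'
#' For a (near) pure-phase specimen, in-focus bright-field contrast is
#' minimal, so the focal plane is the plane with the lowest spatial standard
#' deviation of intensity. Ties are broken toward the central index (logged).
#'
#' @param stack an [image_stack()] with >= 3 planes.
#' @return integer plane index (1-based).
#' @export
find_focal_plane <- function(stack) {
  n <- dim(stack$intensity)[3]
  stopifnot(n >= 3)
  sds <- vapply(seq_len(n), function(j) stats::sd(stack$intensity[, , j]), 0)
  best <- which(sds <= min(sds) + 1e-12 * max(sds, 1))
  if (length(best) > 1) {
    central <- (n + 1) / 2
    best <- best[which.min(abs(best - central))]
    qc_log("focal-plane tie broken toward central index %d", best)
  }
  best[1]
}

#' Select symmetric defocus planes around the focal plane
#'
#' Picks `n_side` planes above and below the focal plane at the requested
#' spacing; oversampled stacks (e.g. 250 nm acquisition steps) are subsampled
#' to the nearest available positions.
#'
#' @param stack an [image_stack()].
#' @param focal focal plane index from [find_focal_plane()]; found
#'   automatically when `NULL`.
#' @param n_side planes on each side of focus.
#' @param spacing desired plane spacing, µm.
#' @return an [image_stack()] with `2 * n_side + 1` planes re-centered so the
#'   focal plane is at offset 0.
#' @export
select_planes <- function(stack, focal = NULL, n_side = 3, spacing = 0.5) {
  if (is.null(focal)) focal <- find_focal_plane(stack)
  z <- stack$z_positions - stack$z_positions[focal]
  want <- seq(-n_side, n_side) * spacing
  idx <- vapply(want, function(w) which.min(abs(z - w)), 0L)
  err <- abs(z[idx] - want)
  tol <- spacing / 2
  if (any(err > tol) || anyDuplicated(idx)) {
    missing <- want[err > tol | duplicated(idx) | duplicated(idx, fromLast = TRUE)]
    stop(sprintf("stack lacks planes near offsets %s um from the focal plane",
                 paste(sprintf("%+.2f", unique(missing)), collapse = ", ")))
  }
  image_stack(stack$intensity[, , idx, drop = FALSE], z[idx],
              stack$pixel_size, stack$wavelength)
}

# Regularized spectral inverse Laplacian. f and the returned matrix are in
# real space; denominator q^2 + eps * mean(q^2), DC term zeroed.
inv_laplacian <- function(f, pixel_size, eps = 1e-3) {
  nr <- nrow(f); nc <- ncol(f)
  q2 <- outer(fft_freq(nr, pixel_size)^2, fft_freq(nc, pixel_size)^2, `+`)
  den <- q2 + eps * mean(q2)
  Fh <- stats::fft(f) / (-den)
  Fh[1, 1] <- 0
  Re(stats::fft(Fh, inverse = TRUE)) / (nr * nc)
}

# Divergence of I * grad(phi) by central differences with replicated edges.
div_I_grad <- function(I, phi, pixel_size) {
  gx <- (phi[, c(2:ncol(phi), ncol(phi))] - phi[, c(1, 1:(ncol(phi) - 1))]) / (2 * pixel_size)
  gy <- (phi[c(2:nrow(phi), nrow(phi)), ] - phi[c(1, 1:(nrow(phi) - 1)), ]) / (2 * pixel_size)
  fx <- I * gx; fy <- I * gy
  dfx <- (fx[, c(2:ncol(fx), ncol(fx))] - fx[, c(1, 1:(ncol(fx) - 1))]) / (2 * pixel_size)
  dfy <- (fy[c(2:nrow(fy), nrow(fy)), ] - fy[c(1, 1:(nrow(fy) - 1)), ]) / (2 * pixel_size)
  dfx + dfy
}

#' Transport-of-intensity phase retrieval
#'
#' Recovers the phase map phi minimizing the transport-of-intensity residual
#' `|| k dI/dz + div(I grad phi) ||` over the field (`k = 2 pi / lambda`).
#' The axial intensity derivative is estimated per pixel by a least-squares
#' slope across all planes; the Laplacian is inverted spectrally with a
#' Tikhonov term, followed by fixed-point refinement of the intensity-weighted
#' divergence. Mirror padding suppresses wrap-around. The mean phase over the
#' image border frame is anchored to zero before background correction.
#'
#' @param planes an [image_stack()] of symmetric defocus planes (>= 3).
#' @param eps Tikhonov regularization as a fraction of the mean squared
#'   spatial frequency of the grid.
#' @param max_iter maximum fixed-point iterations.
#' @param rtol stop when the relative change of the residual norm drops below
#'   this.
#' @param pad mirror-padding width, pixels.
#' @param border width of the border frame used to anchor the phase DC, px.
#' @return a [phase_map()] (not yet background-corrected) with attributes
#'   `residual` (final relative residual) and `iterations`.
#' @export
retrieve_phase <- function(planes, eps = 1e-3, max_iter = 10, rtol = 1e-3,
                           pad = 32, border = 5) {
  z <- planes$z_positions
  stopifnot(length(z) >= 3)
  if (max(abs(z + rev(z))) > 1e-6)
    stop("defocus offsets must be symmetric about focus")
  nr <- dim(planes$intensity)[1]; nc <- dim(planes$intensity)[2]
  k <- 2 * pi / planes$wavelength
  # per-pixel least-squares slope dI/dz over all planes
  zc <- z - mean(z)
  dIdz <- matrix(0, nr, nc)
  for (j in seq_along(z)) dIdz <- dIdz + zc[j] * planes$intensity[, , j]
  dIdz <- dIdz / sum(zc^2)
  Ifoc <- planes$intensity[, , which.min(abs(z))]
  I0 <- mean(Ifoc)
  floor_I <- 1e-6 * I0
  Ifoc[Ifoc < floor_I] <- floor_I
  rhs <- -k * dIdz
  rhs_p <- mirror_pad(rhs, pad)
  I_p <- mirror_pad(Ifoc, pad)
  px <- planes$pixel_size
  phi <- inv_laplacian(rhs_p, px, eps) / I0
  res_prev <- Inf
  iters <- 0L
  rhs_norm <- sqrt(mean(rhs_p^2))
  if (rhs_norm > 0) {
    for (it in seq_len(max_iter)) {
      resid <- rhs_p - div_I_grad(I_p, phi, px)
      res <- sqrt(mean(resid^2)) / rhs_norm
      iters <- it
      if (abs(res_prev - res) < rtol * max(res, 1e-12)) break
      phi <- phi + inv_laplacian(resid, px, eps) / I0
      res_prev <- res
    }
    if (iters == max_iter)
      qc_log("TIE fixed-point refinement stopped at max_iter (rel. residual %.3g)", res)
  } else res <- 0
  phi <- crop_pad(phi, pad, nr, nc)
  # anchor DC to the border frame
  bmask <- matrix(FALSE, nr, nc)
  bmask[c(seq_len(border), nr - seq_len(border) + 1), ] <- TRUE
  bmask[, c(seq_len(border), nc - seq_len(border) + 1)] <- TRUE
  phi <- phi - mean(phi[bmask])
  out <- phase_map(phi, px, background_corrected = FALSE)
  attr(out, "residual") <- if (rhs_norm > 0) res else 0
  attr(out, "iterations") <- iters
  out
}

#' Background-correct a phase map
#'
#' Builds a histogram of the phase values (256 bins over the 1st to 99th
#' percentile range), fits a Gaussian by least squares to the tallest peak
#' +/- 5 bins, and subtracts the fitted center so the background mode sits at
#' zero. Falls back to plain mode subtraction if the fit fails.
#'
#' @param map a [phase_map()]; the field should contain background pixels
#'   (>= ~30%).
#' @param nbins histogram bins.
#' @return the corrected [phase_map()] with `background_corrected = TRUE` and
#'   attribute `background_center` (the subtracted value, radians).
#' @export
background_correct <- function(map, nbins = 256) {
  v <- as.vector(map$phase)
  rng <- stats::quantile(v, c(0.01, 0.99), names = FALSE)
  if (rng[2] <= rng[1]) rng <- range(v) + c(-1e-6, 1e-6)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- graphics::hist(v[v >= rng[1] & v <= rng[2]], breaks = breaks, plot = FALSE)
  peak <- which.max(h$counts)
  win <- max(1, peak - 5):min(nbins, peak + 5)
  xs <- h$mids[win]; ys <- h$counts[win]
  center <- tryCatch({
    fit <- suppressWarnings(stats::nls(
      ys ~ a * exp(-(xs - mu)^2 / (2 * s^2)),
      start = list(a = max(ys), mu = h$mids[peak],
                   s = max(diff(h$mids)[1] * 2, stats::sd(xs) / 2)),
      control = stats::nls.control(warnOnly = TRUE)))
    stats::coef(fit)[["mu"]]
  }, error = function(e) {
    qc_log("background Gaussian fit failed (%s); using histogram mode", conditionMessage(e))
    h$mids[peak]
  })
  out <- phase_map(map$phase - center, map$pixel_size,
                   background_corrected = TRUE, provenance = map$provenance)
  attr(out, "background_center") <- center
  out
}
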