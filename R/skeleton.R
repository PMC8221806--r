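# Minimum-area bounding rectangle of a polygon via rotating calipers over
# convex-hull edge directions. Returns center, unit long-axis direction and
# half-extents.
min_area_rect <- function(xy) {
  h <- grDevices::chull(xy)
  hp <- xy[h, , drop = FALSE]
  nh <- nrow(hp)
  best <- NULL
  for (i in seq_len(nh)) {
    e <- hp[(i %% nh) + 1, ] - hp[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len
    n <- c(-u[2], u[1])
    su <- xy %*% u; sn <- xy %*% n
    area <- diff(range(su)) * diff(range(sn))
    if (is.null(best) || area < best$area) {
      best <- list(area = area, u = u, n = n,
                   su = range(su), sn = range(sn))
    }
  }
  long_first <- diff(best$su) >= diff(best$sn)
  u <- if (long_first) best$u else best$n
  v <- if (long_first) best$n else best$u
  ctr <- mean(best$su) * best$u + mean(best$sn) * best$n
  list(center = ctr, axis = u, normal = v,
       half_long = max(diff(best$su), diff(best$sn)) / 2,
       half_short = min(diff(best$su), diff(best$sn)) / 2)
}

# Intersection parameters t of the line p + t*dir with the edges of a closed
# polygon, sorted ascending.
line_polygon_hits <- function(p, dir, xy) {
  a <- xy
  b <- xy[c(2:nrow(xy), 1), , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  den <- dir[1] * (-ey) - dir[2] * (-ex)
  wx <- a[, 1] - p[1]; wy <- a[, 2] - p[2]
  t <- (wx * (-ey) - wy * (-ex)) / den
  s <- (dir[1] * wy - dir[2] * wx) / den
  ok <- is.finite(t) & s >= 0 & s < 1
  sort(t[ok])
}

# Two hits bracketing t = 0 (the usual case); falls back to the two smallest
# |t| hits when the query point lies outside the polygon.
bracket_hits <- function(hits) {
  if (length(hits) < 2) return(NULL)
  neg <- hits[hits < 0]; pos <- hits[hits >= 0]
  if (length(neg) && length(pos)) return(c(max(neg), min(pos)))
  h <- hits[order(abs(hits))][1:2]
  sort(h)
}

segments_cross <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-12) return(FALSE)
  w <- p2 - p1
  t <- (w[1] * d2[2] - w[2] * d2[1]) / den
  s <- (w[1] * d1[2] - w[2] * d1[1]) / den
  t > 0 && t < 1 && s > 0 && s < 1
}

smooth_runmean <- function(m, k = 5) {
  if (nrow(m) < k) return(m)
  out <- m
  half <- k %/% 2
  for (j in 1:2) {
    cs <- cumsum(c(0, m[, j]))
    n <- nrow(m)
    lo <- pmax(0, seq_len(n) - half - 1)
    hi <- pmin(n, seq_len(n) + half)
    out[, j] <- (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
  }
  out
}

#' Skeletonize a cell contour by perpendicular sectioning
#'
#' Builds the cell centerline iteratively: the minimum-area bounding rectangle
#' defines the initial long axis; section lines are drawn every `section_um`
#' perpendicular to the axis and clipped to the contour; the centerline is
#' updated to run through the section midpoints; section directions are then
#' re-estimated perpendicular to the local centerline, and sections crossing a
#' neighboring section are removed. Iterated to convergence.
#'
#' @param contour a contour from [cell_contours()] (list with `xy`, `label`),
#'   or a plain 2-column matrix of polygon vertices in µm.
#' @param section_um section spacing, µm.
#' @param max_iter maximum refinement iterations.
#' @param min_aspect below this contour aspect ratio the rectangle axis is
#'   used without refinement (logged).
#' @return object of class `cell_skeleton`: list with `mid` (section midpoints,
#'   µm), `dir` (unit section directions), `r` (half-widths, µm), `s`
#'   (arclength of each section from tip A, µm), `spacing`, `cap_extent`
#'   (named c(A, B), µm), `tips` (2 x 2 matrix, rows A and B, µm), `length`
#'   (tip-to-tip, µm), `label`.
#' @export
skeletonize_cell <- function(contour, section_um = 0.25, max_iter = 6,
                             min_aspect = 1.5) {
  xy <- if (is.list(contour)) contour$xy else contour
  label <- if (is.list(contour)) contour$label else NA_integer_
  stopifnot(is.matrix(xy), ncol(xy) == 2, nrow(xy) >= 8)
  rect <- min_area_rect(xy)
  aspect <- rect$half_long / rect$half_short
  refine <- aspect >= min_aspect
  if (!refine)
    qc_log("contour aspect ratio %.2f < %.1f; using rectangle axis without refinement",
           aspect, min_aspect)
  u <- rect$axis
  su <- as.vector(xy %*% u)
  smin <- min(su); smax <- max(su)
  spos <- seq(smin + section_um / 2, smax - section_um / 2, by = section_um)
  ref <- sum(rect$center * u)
  mids <- cbind(rect$center[1] + (spos - ref) * u[1],
                rect$center[2] + (spos - ref) * u[2])
  dirs <- matrix(rep(rect$normal, each = length(spos)), ncol = 2)
  r <- rep(NA_real_, length(spos))
  n_iter <- if (refine) max_iter else 1L
  for (it in seq_len(n_iter)) {
    newmids <- mids
    for (i in seq_along(spos)) {
      br <- bracket_hits(line_polygon_hits(mids[i, ], dirs[i, ], xy))
      if (is.null(br)) { r[i] <- NA; next }
      newmids[i, ] <- mids[i, ] + mean(br) * dirs[i, ]
      r[i] <- diff(br) / 2
    }
    ok <- !is.na(r) & r > 0
    newmids <- newmids[ok, , drop = FALSE]
    r <- r[ok]
    spos <- spos[ok]
    moved <- if (nrow(newmids) == nrow(mids)) max(sqrt(rowSums((newmids - mids)^2))) else Inf
    sm <- smooth_runmean(newmids, 5)
    # tangents by central differences of the smoothed centerline
    n <- nrow(sm)
    tang <- rbind(sm[2, ] - sm[1, ],
                  sm[3:n, ] - sm[1:(n - 2), ],
                  sm[n, ] - sm[n - 1, ])
    tl <- sqrt(rowSums(tang^2)); tl[tl == 0] <- 1
    tang <- tang / tl
    mids <- newmids
    dirs <- cbind(-tang[, 2], tang[, 1])
    r <- r
    if (refine && moved < 0.005) break
  }
  # drop sections crossing the previously kept neighbor
  keep <- rep(TRUE, nrow(mids))
  last <- 1
  for (i in seq_len(nrow(mids))[-1]) {
    p1 <- mids[last, ] - r[last] * dirs[last, ]; q1 <- mids[last, ] + r[last] * dirs[last, ]
    p2 <- mids[i, ] - r[i] * dirs[i, ];          q2 <- mids[i, ] + r[i] * dirs[i, ]
    if (segments_cross(p1, q1, p2, q2)) keep[i] <- FALSE else last <- i
  }
  if (any(!keep)) qc_log("removed %d crossing section(s)", sum(!keep))
  mids <- mids[keep, , drop = FALSE]; dirs <- dirs[keep, , drop = FALSE]
  r <- r[keep]; spos <- spos[keep]
  m <- nrow(mids)
  if (m < 3) stop("skeletonization failed: fewer than 3 valid sections")
  # canonical orientation: end A is the lexicographically smaller tip, so
  # repeated runs on the same cell agree on which end is which
  if (mids[1, 1] > mids[m, 1] ||
      (mids[1, 1] == mids[m, 1] && mids[1, 2] > mids[m, 2])) {
    mids <- mids[m:1, , drop = FALSE]
    dirs <- dirs[m:1, , drop = FALSE]
    r <- rev(r); spos <- rev(spos)
  }
  # cap extents: farthest contour point along the outward centerline direction
  outA <- (mids[1, ] - mids[min(3, m), ]); outA <- outA / sqrt(sum(outA^2))
  outB <- (mids[m, ] - mids[max(1, m - 2), ]); outB <- outB / sqrt(sum(outB^2))
  capA <- max((xy[, 1] - mids[1, 1]) * outA[1] + (xy[, 2] - mids[1, 2]) * outA[2])
  capB <- max((xy[, 1] - mids[m, 1]) * outB[1] + (xy[, 2] - mids[m, 2]) * outB[2])
  capA <- max(capA, 0); capB <- max(capB, 0)
  seg <- sqrt(rowSums((mids[-1, , drop = FALSE] - mids[-m, , drop = FALSE])^2))
  s <- capA + c(0, cumsum(seg))
  len <- capA + sum(seg) + capB
  tips <- rbind(A = mids[1, ] + capA * outA, B = mids[m, ] + capB * outB)
  structure(list(mid = mids, dir = dirs, r = r, s = s, spacing = section_um,
                 cap_extent = c(A = capA, B = capB), tips = tips,
                 length = len, label = label, contour = xy),
            class = "cell_skeleton")
}

#' @export
print.cell_skeleton <- function(x, ...) {
  cat(sprintf("<cell_skeleton> %d sections @ %.2f um, length %.2f um, mean width %.2f um\n",
              length(x$r), x$spacing, x$length, 2 * mean(x$r)))
  invisible(x)
}

#' Volume and surface area from a skeleton
#'
#' Sums per-section solids of revolution (`V_i = pi r_i^2 d`, lateral area
#' `A_i = 2 pi r_i d`) over the cylindrical span and closes each pole with a
#' regular spherical cap. The cap junction at each end is the first section
#' (walking inward from the tip) whose distance to the tip is at least its
#' half-width — for an ideal spherocylinder this is exactly the
#' cylinder/hemisphere tangent point. Cap base radius is the junction
#' half-width; cap height is the tip distance at the junction (less half a
#' section so cylinder disks and cap do not overlap).
#'
#' @param skeleton a [skeletonize_cell()] result.
#' @return object of class `cell_geometry`: list with `length` (µm),
#'   `mean_width` (µm), `volume` (fL), `surface_area` (µm²) plus the cap
#'   parameters used.
#' @export
compute_geometry <- function(skeleton) {
  sk <- skeleton
  d <- sk$spacing
  m <- length(sk$r)
  dist_tipA <- sk$s
  dist_tipB <- sk$length - sk$s
  jA <- which(dist_tipA >= sk$r)[1]
  jB <- rev(which(dist_tipB >= sk$r))[1]
  if (is.na(jA)) jA <- 1L
  if (is.na(jB)) jB <- m
  if (jB < jA) { jA <- 1L; jB <- m }
  cyl <- jA:jB
  capA <- list(a = sk$r[jA], h = max(dist_tipA[jA] - d / 2, 0))
  capB <- list(a = sk$r[jB], h = max(dist_tipB[jB] - d / 2, 0))
  cap_vol <- function(cp) pi * cp$h * (3 * cp$a^2 + cp$h^2) / 6
  cap_area <- function(cp) pi * (cp$a^2 + cp$h^2)
  vol <- sum(pi * sk$r[cyl]^2 * d) + cap_vol(capA) + cap_vol(capB)
  area <- sum(2 * pi * sk$r[cyl] * d) + cap_area(capA) + cap_area(capB)
  structure(list(length = sk$length, mean_width = 2 * mean(sk$r[cyl]),
                 volume = vol, surface_area = area,
                 cap_A = capA, cap_B = capB, junctions = c(jA, jB)),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("<cell_geometry> L=%.2f um, w=%.2f um, V=%.2f fL, A=%.2f um^2\n",
              x$length, x$mean_width, x$volume, x$surface_area))
  invisible(x)
}
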