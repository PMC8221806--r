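test_that("spherocylinder skeleton recovers length and section widths", {
  sk <- skeletonize_cell(list(xy = sphero_contour(10, 2), label = 1L))
  expect_lt(abs(sk$length - 10), 0.11)
  cyl <- sk$s > 2.2 & sk$s < 7.8
  expect_true(all(abs(sk$r[cyl] - 2) < 0.05))
  # rotation invariance
  sk30 <- skeletonize_cell(list(xy = sphero_contour(10, 2, angle = 30,
                                                    center = c(20, 20)),
                                label = 1L))
  expect_lt(abs(sk30$length / sk$length - 1), 0.01)
  g0 <- compute_geometry(sk); g30 <- compute_geometry(sk30)
  expect_lt(abs(g30$volume / g0$volume - 1), 0.01)
  expect_lt(abs(g30$mean_width / g0$mean_width - 1), 0.01)
})

test_that("curved (banana) centerline arclength matches the generating arc", {
  R0 <- 10; half <- 0.5; r <- 1.9   # arc length 10 um
  tt <- seq(-half, half, length.out = 150)
  inner <- cbind((R0 - r) * sin(tt), (R0 - r) * cos(tt))
  outer_arc <- cbind((R0 + r) * sin(rev(tt)), (R0 + r) * cos(rev(tt)))
  th <- seq(-pi / 2, pi / 2, length.out = 60)
  cap_at <- function(ang, sgn) {
    ctr <- c(R0 * sin(ang), R0 * cos(ang))
    tang <- sgn * c(cos(ang), -sin(ang))
    radial <- c(sin(ang), cos(ang))
    t(vapply(th, function(a) ctr + r * cos(a) * tang + r * sin(a) * radial,
             c(0, 0)))
  }
  poly <- rbind(inner, cap_at(half, +1), outer_arc, cap_at(-half, -1))
  sk <- skeletonize_cell(list(xy = poly, label = 1L))
  expect_lt(abs(sk$length - (10 + 2 * r)) / (10 + 2 * r), 0.02)
})

test_that("geometry matches closed forms and the scaling laws", {
  g1 <- compute_geometry(skeletonize_cell(list(xy = sphero_contour(10, 2),
                                               label = 1L)))
  expect_lt(abs(g1$volume / 108.909 - 1), 0.02)
  expect_lt(abs(g1$surface_area / 125.664 - 1), 0.02)
  # doubling all linear dimensions: volume x8, area x4
  g2 <- compute_geometry(skeletonize_cell(list(xy = sphero_contour(20, 4),
                                               label = 1L)))
  expect_lt(abs(g2$volume / (8 * g1$volume) - 1), 0.02)
  expect_lt(abs(g2$surface_area / (4 * g1$surface_area) - 1), 0.02)
})

test_that("tapered solid of revolution matches the quadrature oracle", {
  tc <- tapered_contour(12, 2.1, 1.5)
  sk <- skeletonize_cell(list(xy = tc$xy, label = 1L))
  geo <- compute_geometry(sk)
  expect_lt(abs(geo$volume / tc$volume - 1), 0.02)
})

test_that("randomized spherocylinders meet the geometry oracle", {
  set.seed(101)
  for (i in 1:20) {
    L <- runif(1, 6, 16); r <- runif(1, 1.5, 2.3); ang <- runif(1, 0, 180)
    xy <- sphero_contour(L, r, angle = ang, center = c(20, 20))
    geo <- compute_geometry(skeletonize_cell(list(xy = xy, label = 1L)))
    V <- pi * r^2 * (L - 2 * r) + 4 / 3 * pi * r^3
    A <- 2 * pi * r * (L - 2 * r) + 4 * pi * r^2
    expect_lt(abs(geo$volume / V - 1), 0.02)
    expect_lt(abs(geo$surface_area / A - 1), 0.02)
    expect_lt(abs(geo$length - L), 0.1075)
  }
})

test_that("segmentation finds phantoms and matches projected area", {
  g <- phantom_grid(nx = 256, ny = 256)
  sp <- phantom_spec(length = 10, radius = 1.9, angle = 15, center = c(13.5, 13.5),
                     base_density = 282)
  pm <- phase_from_density(sp, g)
  pm$background_corrected <- TRUE
  mask <- segment_cells(pm)
  expect_equal(max(mask), 1L)
  A_true <- 2 * 1.9 * (10 - 2 * 1.9) + pi * 1.9^2
  expect_lt(abs(sum(mask > 0) * g$pixel_size^2 / A_true - 1), 0.05)
  # empty map
  empty <- phase_map(matrix(0, 64, 64), 0.1075, background_corrected = TRUE)
  expect_equal(max(segment_cells(empty)), 0L)
  # two separated phantoms give two labels
  sp2 <- phantom_spec(length = 8, radius = 1.7, angle = -10, center = c(13.5, 6),
                      base_density = 282)
  pm2 <- phase_from_density(sp2, g)
  both <- phase_map(pm$phase + pm2$phase, g$pixel_size,
                    background_corrected = TRUE)
  expect_equal(max(segment_cells(both)), 2L)
})

test_that("mass identity and the worked mass example hold", {
  m <- phase_map(matrix(0.1, 4, 4), 0.1, background_corrected = TRUE)
  expect_equal(282 * 108.9 * 1e-3, 30.71, tolerance = 1e-3)
  g <- phantom_grid(nx = 256, ny = 256)
  sp <- phantom_spec(length = 10, radius = 1.9, angle = 15, center = c(13.5, 13.5),
                     base_density = 250)
  run <- calibrated_run(sp, g, mode = "angular")
  ms <- run$measurements
  expect_equal(ms$mass_pg, ms$density_mg_ml * ms$volume_fl * 1e-3,
               tolerance = 1e-12)
  expect_lt(abs(ms$density_mg_ml / 250 - 1), 0.05)
  # mass conservation through segmentation, noiseless
  expect_lt(abs(ms$mass_pg / phantom_truth(sp)$mass - 1), 0.05)
})

# --- polar density and septum, on constructed density maps ----------------

make_cell_fixture <- function(L = 12, r = 1.9, px = 0.1075, n = 200,
                              base = 250) {
  ctr <- c(n * px / 2, n * px / 2)
  xy <- sphero_contour(L, r, center = ctr)
  sk <- skeletonize_cell(list(xy = xy, label = 1L))
  co <- (seq_len(n) - 0.5) * px
  X <- matrix(rep(co, each = n), n, n)
  Y <- matrix(rep(co, times = n), n, n)
  d <- abs(Y - ctr[2])
  along <- X - (ctr[1] - L / 2)
  inside <- matrix(FALSE, n, n)
  idx <- which(d <= r & along >= 0 & along <= L, arr.ind = TRUE)
  # proper capsule test
  dd <- vapply(seq_len(n * n), function(k) {
    qpicell:::dist_to_segment(X[k], Y[k], ctr - c(L / 2 - r, 0), ctr + c(L / 2 - r, 0))
  }, 0)
  inside <- matrix(dd <= r, n, n)
  dmap <- matrix(NA_real_, n, n)
  dmap[inside] <- base
  list(mask = inside, sk = sk, dmap = dmap, px = px, X = X, Y = Y,
       ctr = ctr, L = L, r = r)
}

test_that("polar density mode recovers uniform and contaminated regions", {
  fx <- make_cell_fixture()
  expect_lt(abs(polar_density(fx$dmap, fx$mask, fx$sk, "A", pixel_size = fx$px) - 250), 2)
  # 10% droplet pixels at 400 shift the mean but not the mode
  dmap2 <- fx$dmap
  reg <- which(fx$mask & fx$X < fx$ctr[1] - fx$L / 2 + 3)
  set.seed(7)
  hot <- sample(reg, length(reg) %/% 10)
  dmap2[reg] <- 260
  dmap2[hot] <- 400
  mode_est <- polar_density(dmap2, fx$mask, fx$sk, "A", pixel_size = fx$px)
  expect_lt(abs(mode_est - 260), 2)
  mean_est <- mean(dmap2[reg])
  expect_gt(abs(mean_est - 260), 4)   # the mean shifts by > 2 bins
})

test_that("axial density gradient appears as a polar mode difference", {
  fx <- make_cell_fixture()
  grad <- -3
  s_pix <- fx$X - (fx$ctr[1] - fx$L / 2)
  dmap <- fx$dmap
  dmap[fx$mask] <- 282 + grad * (s_pix[fx$mask] - fx$L / 2)
  pA <- polar_density(dmap, fx$mask, fx$sk, "A", pixel_size = fx$px)
  pB <- polar_density(dmap, fx$mask, fx$sk, "B", pixel_size = fx$px)
  # voxel-average oracle: region centroids are (L - 3) um apart
  expect_equal(pA - pB, -grad * (fx$L - 3), tolerance = 0.15 * abs(grad * (fx$L - 3)))
  expect_gt(pA - pB, 0)   # old end denser for a negative old->new gradient
})

paint_septum <- function(fx, sag = 0, rho_sep = 400, rho_A = NULL, rho_B = NULL,
                         width = 0.4) {
  dmap <- fx$dmap
  if (!is.null(rho_A)) dmap[fx$mask & fx$X < fx$ctr[1]] <- rho_A
  if (!is.null(rho_B)) dmap[fx$mask & fx$X >= fx$ctr[1]] <- rho_B
  # arc septum: chord at the cell mid-plane, bulging toward -x (pole A) for
  # positive sag
  u <- (fx$Y - fx$ctr[2]) / fx$r
  xc <- fx$ctr[1] - sag * (1 - u^2)
  band <- fx$mask & abs(fx$X - xc) <= width / 2 & abs(u) <= 1
  dmap[band] <- rho_sep
  dmap
}

test_that("straight septa are flat; arc septa report sagitta and direction", {
  fx <- make_cell_fixture()
  flat <- measure_septum_bend(paint_septum(fx, sag = 0), fx$mask, fx$sk, fx$px)
  expect_false(is.null(flat))
  expect_equal(flat$toward, "flat")
  expect_lt(abs(flat$sagitta), 0.15)
  bent <- measure_septum_bend(paint_septum(fx, sag = 0.5), fx$mask, fx$sk, fx$px)
  expect_equal(bent$toward, "A")
  expect_lt(abs(abs(bent$sagitta) - 0.5), 0.1)
  expect_lt(abs(bent$position - 0.5), 0.05)
})

test_that("septum bowed toward the lighter compartment is classified as such", {
  fx <- make_cell_fixture()
  # A denser (300) than B (260), septum bowed toward B (away from denser A)
  dmap <- paint_septum(fx, sag = -0.5, rho_A = 300, rho_B = 260)
  res <- measure_septum_bend(dmap, fx$mask, fx$sk, fx$px)
  expect_equal(res$toward, "B")
  expect_gt(res$rho_A, res$rho_B)
  # i.e. bent away from the denser compartment
  away <- (res$toward == "B" && res$rho_A > res$rho_B) ||
    (res$toward == "A" && res$rho_B > res$rho_A)
  expect_true(away)
})
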