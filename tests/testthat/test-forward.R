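test_that("phase follows the refractive-increment projection formula", {
  # uniform slab: 0.282 g/mL over a 3.8 um path at alpha = 0.18, 680 nm
  arr <- array(282, dim = c(8, 8, 4))
  occ <- array(1, dim = c(8, 8, 4))
  vol <- structure(arr, pixel_size = 0.1, z_step = 0.95, origin = c(0, 0),
                   occupancy = occ, class = "density_volume")
  pm <- phase_from_density(vol, wavelength = 0.68, refractive_increment = 0.18)
  expect_equal(pm$phase[1, 1], (2 * pi / 0.68) * 0.18 * 0.282 * 3.8,
               tolerance = 1e-12)
  # empty volume: identically zero phase
  vol0 <- structure(array(0, dim = c(8, 8, 4)), pixel_size = 0.1, z_step = 0.95,
                    origin = c(0, 0), occupancy = occ, class = "density_volume")
  expect_true(all(phase_from_density(vol0)$phase == 0))
})

test_that("projection is linear: stacked inclusions equal one of double density", {
  base <- array(0, dim = c(8, 8, 4))
  occ <- array(1, dim = c(8, 8, 4))
  two <- base; two[4, 4, 2] <- 300; two[4, 4, 3] <- 300
  one <- base; one[4, 4, 2] <- 600
  as_vol <- function(a) structure(a, pixel_size = 0.1, z_step = 0.5,
                                  origin = c(0, 0), occupancy = occ,
                                  class = "density_volume")
  expect_equal(phase_from_density(as_vol(two))$phase,
               phase_from_density(as_vol(one))$phase, tolerance = 1e-12)
})

test_that("zero phase gives uniform planes; fixed seed is deterministic", {
  pm <- phase_map(matrix(0, 64, 64), 0.1075)
  st <- simulate_stack(pm, mode = "angular")
  for (j in seq_along(st$z_positions))
    expect_lt(diff(range(st$intensity[, , j])), 1e-9)
  st1 <- simulate_stack(pm, noise_sigma = 0.01, seed = 42)
  st2 <- simulate_stack(pm, noise_sigma = 0.01, seed = 42)
  expect_identical(st1$intensity, st2$intensity)
  # noiseless repeat calls are bitwise identical too
  expect_identical(simulate_stack(pm)$intensity, simulate_stack(pm)$intensity)
})

test_that("offsets must be symmetric and include focus", {
  pm <- phase_map(matrix(0, 32, 32), 0.1075)
  expect_error(simulate_stack(pm, z_offsets = c(-1, 0, 0.5)), "symmetric")
  expect_error(simulate_stack(pm, z_offsets = c(-1, -0.5, 0.5, 1)), "symmetric")
})

test_that("weak-phase defocus contrast is proportional to the phase Laplacian", {
  px <- 0.1075; n <- 128
  co <- (seq_len(n) - 0.5) * px
  g <- outer(co, co, function(y, x) exp(-((x - 6.9)^2 + (y - 6.9)^2) / (2 * 1.2^2)))
  phi <- 0.2 * g
  pm <- phase_map(phi, px)
  st <- simulate_stack(pm, z_offsets = c(-1.5, -1, -0.5, 0, 0.5, 1, 1.5),
                       mode = "angular")
  dz <- 0.5
  diff_meas <- st$intensity[, , 5] - st$intensity[, , 3]   # +0.5 vs -0.5 um
  # finite-difference Laplacian oracle
  lap <- matrix(0, n, n)
  lap[2:(n - 1), 2:(n - 1)] <-
    (phi[1:(n - 2), 2:(n - 1)] + phi[3:n, 2:(n - 1)] +
       phi[2:(n - 1), 1:(n - 2)] + phi[2:(n - 1), 3:n] -
       4 * phi[2:(n - 1), 2:(n - 1)]) / px^2
  k <- 2 * pi / 0.68
  pred <- -(2 * dz / k) * lap
  inner <- 8:(n - 8)
  err <- diff_meas[inner, inner] - pred[inner, inner]
  expect_lt(sqrt(mean(err^2)) / sqrt(mean(pred[inner, inner]^2)), 0.10)
})

test_that("in-focus plane of a pure-phase object has minimal contrast", {
  px <- 0.1075; n <- 128
  co <- (seq_len(n) - 0.5) * px
  g <- outer(co, co, function(y, x) exp(-((x - 6.9)^2 + (y - 6.9)^2) / (2 * 1.2^2)))
  st <- simulate_stack(phase_map(0.4 * g, px), mode = "angular")
  sds <- apply(st$intensity, 3, sd)
  expect_equal(which.min(sds), which(st$z_positions == 0))
})
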