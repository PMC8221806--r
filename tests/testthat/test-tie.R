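make_blob_map <- function(peak = 0.2, sigma = 1.0, n = 160, px = 0.1075) {
  co <- (seq_len(n) - 0.5) * px
  c0 <- n * px / 2
  phase_map(peak * outer(co, co, function(y, x)
    exp(-((x - c0)^2 + (y - c0)^2) / (2 * sigma^2))), px)
}

test_that("focal plane is the minimum-contrast plane; ties go central", {
  st <- simulate_stack(make_blob_map(), mode = "angular")
  expect_equal(find_focal_plane(st), 4L)   # 7 planes, 0 offset central
  flat <- image_stack(array(1, dim = c(16, 16, 5)), -2:2, 0.1, 0.68)
  expect_equal(find_focal_plane(flat), 3L)
  arr <- array(0, dim = c(16, 16, 5))
  for (j in c(1, 2, 3, 5)) arr[, , j] <- matrix(runif(256), 16, 16)
  arr[, , 4] <- 1
  st2 <- image_stack(arr, -2:2, 0.1, 0.68)
  expect_equal(find_focal_plane(st2), 4L)
})

test_that("oversampled stacks are subsampled to the requested plane spacing", {
  # 25 planes at 250 nm (acquisition oversampling), focal at the center
  arr <- array(1, dim = c(8, 8, 25))
  st <- image_stack(arr, seq(-3, 3, by = 0.25), 0.1075, 0.68)
  sub <- select_planes(st, focal = 13L)
  expect_equal(length(sub$z_positions), 7L)
  expect_equal(sub$z_positions, seq(-1.5, 1.5, by = 0.5))
  # already-selected 7-plane stack is the identity
  st7 <- image_stack(array(1, dim = c(8, 8, 7)), seq(-1.5, 1.5, 0.5), 0.1075, 0.68)
  expect_equal(select_planes(st7, focal = 4L)$z_positions, st7$z_positions)
  # focal too close to the stack boundary: explicit error
  expect_error(select_planes(st, focal = 2L), "offsets")
})

test_that("uniform stacks retrieve zero phase", {
  st <- image_stack(array(2.5, dim = c(64, 64, 7)), seq(-1.5, 1.5, 0.5),
                    0.1075, 0.68)
  rec <- retrieve_phase(st)
  expect_lt(max(abs(rec$phase)), 1e-9)
})

test_that("retrieval is invariant to the intensity scale (camera gain)", {
  st <- simulate_stack(make_blob_map(), mode = "angular")
  st2 <- st
  st2$intensity <- st$intensity * 37.5
  r1 <- retrieve_phase(st)
  r2 <- retrieve_phase(st2)
  expect_equal(r1$phase, r2$phase, tolerance = 1e-9)
})

test_that("weak-phase round trip recovers the phantom phase field", {
  pm <- make_blob_map(peak = 0.2, sigma = 1.0)
  for (mode in c("angular", "linear")) {
    st <- simulate_stack(pm, mode = mode)
    rec <- background_correct(retrieve_phase(st))
    err <- rec$phase - pm$phase
    expect_lt(sqrt(mean(err^2)) / max(pm$phase), 0.05)
    expect_gt(cor(as.vector(rec$phase), as.vector(pm$phase)), 0.98)
  }
})

test_that("background correction removes offsets and is idempotent", {
  set.seed(5)
  n <- 128
  phi <- matrix(rnorm(n * n, 0.2, 0.01), n, n)
  cell <- matrix(FALSE, n, n); cell[40:90, 40:90] <- TRUE   # 16% cell pixels
  phi[cell] <- rnorm(sum(cell), 0.8, 0.05)
  pm <- phase_map(phi, 0.1075)
  bc <- background_correct(pm)
  # background peak centered at zero within half a histogram bin
  bin <- diff(quantile(phi, c(0.01, 0.99))) / 256
  expect_lt(abs(median(bc$phase[!cell])), bin / 2)
  expect_true(bc$background_corrected)
  # shift equivariance
  pm2 <- phase_map(phi + 0.3, 0.1075)
  bc2 <- background_correct(pm2)
  expect_lt(max(abs(bc2$phase - bc$phase)), bin / 2)
  # idempotence
  bc3 <- background_correct(bc)
  expect_lt(max(abs(bc3$phase - bc$phase)), bin / 2)
})
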