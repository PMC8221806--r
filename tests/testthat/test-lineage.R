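rec <- function(x, y, area, label = 1L, frame = 1L) {
  data.frame(frame = frame, label = label, centroid_x = x, centroid_y = y,
             area_um2 = area)
}

test_that("linking obeys the distance and area rules", {
  px <- 0.1075
  # 11.2 px apart, area ratio 75%: linked
  a <- rec(100 * px, 100 * px, 2000 * px^2)
  b <- rec(110 * px, 105 * px, 1500 * px^2)
  expect_equal(link_frames(a, b, px), 1L)
  # area ratio 65%: not linked even at 5 px
  b2 <- rec(103 * px, 104 * px, 1300 * px^2)
  expect_true(is.na(link_frames(a, b2, px)))
  # 25 px apart, equal areas: not linked
  b3 <- rec(125 * px, 100 * px, 2000 * px^2)
  expect_true(is.na(link_frames(a, b3, px)))
})

test_that("simulated time-lapse links and divisions are fully recovered", {
  tl <- timelapse_spec(interval_min = 5, n_frames = 24, cycle_min = 150,
                       seed = 3)
  cells <- list(seed_cell(center = c(14, 6), length = 9, age = 0),
                seed_cell(center = c(14, 14), length = 10, age = 95),
                seed_cell(center = c(14, 22), length = 11, age = 110))
  sim <- simulate_timelapse(tl, cells, phantom_grid(nx = 280, ny = 280),
                            render = "none")
  recs <- truth_records(sim$truth)
  lin <- build_lineage(recs)
  # every pipeline track maps to exactly one true cell and vice versa
  key <- paste(lin$measurements$frame, lin$measurements$label)
  truth_key <- paste(sim$truth$frame, sim$truth$cell)
  true_cell <- sim$truth$cell[match(key, truth_key)]
  tab <- table(lin$measurements$track, true_cell)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
  # both true divisions found with the right parent
  expect_equal(nrow(lin$divisions), 2L)
  for (i in 1:2) {
    dv <- lin$divisions[i, ]
    pa_true <- unique(true_cell[lin$measurements$track == dv$parent])
    d1_true <- unique(true_cell[lin$measurements$track == dv$daughter1])
    expect_equal(unique(sim$truth$parent[sim$truth$cell == d1_true]), pa_true)
  }
  # daughter mass additivity at division
  sep <- separation_event_change(lin)
  expect_equal(nrow(sep), 2L)
  expect_lt(max(abs(sep$dvolume_pct - 5)), 0.2)
})

test_that("cycle alignment preserves endpoints and interpolates linearly", {
  tm <- data.frame(frame = 1:11,
                   volume_fl = seq(80, 120, length.out = 11),
                   density_mg_ml = seq(267, 250, length.out = 11),
                   mass_pg = seq(21, 30, length.out = 11))
  al <- align_to_cycle(tm, grid_points = 50)
  expect_equal(al$density_mg_ml[1], 267)
  expect_equal(al$density_mg_ml[50], 250)
  expect_lt(max(abs(diff(al$density_mg_ml) - diff(al$density_mg_ml)[1])), 1e-9)
  # short tracks are excluded
  expect_null(align_to_cycle(tm[1:3, ], grid_points = 50))
})

test_that("population SD is zero for identical tracks", {
  tm <- data.frame(frame = 1:10, volume_fl = 1:10, density_mg_ml = 260,
                   mass_pg = seq(20, 29))
  a1 <- align_to_cycle(tm); a2 <- align_to_cycle(tm)
  sds <- apply(cbind(a1$volume_fl, a2$volume_fl), 1, sd)
  expect_true(all(sds == 0))
})

test_that("aligned density shows the cell-cycle signature", {
  # one full cycle observed birth-to-division under defaults
  tl <- timelapse_spec(interval_min = 5, n_frames = 60, cycle_min = 150,
                       seed = 5)
  cells <- list(seed_cell(center = c(20, 10), length = 13.5, age = 145))
  sim <- simulate_timelapse(tl, cells, phantom_grid(nx = 560, ny = 190),
                            render = "none")
  lin <- build_lineage(truth_records(sim$truth))
  # the first division yields daughters observed through their whole cycle
  traj <- population_trajectories(lin, grid_points = 50)
  expect_false(is.null(traj))
  dens <- traj$density_mean
  growth_end <- round(50 * (1 - tl$division_fraction))
  expect_lt(dens[growth_end], dens[1])                 # falls through growth
  expect_gt(dens[50], dens[growth_end])                # rises in division phase
  # and drops at separation
  sep <- separation_event_change(lin)
  expect_true(all(sep$ddensity_pct < 0))
})
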