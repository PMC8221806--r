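test_that("growth fits identify exponential and linear series", {
  t <- seq(0, 300, by = 10)
  fe <- fit_mass_growth(t, 2 * exp(0.003 * t))
  expect_equal(fe$preferred, "exponential")
  expect_lt(abs(fe$exponential$rate / 0.003 - 1), 0.01)
  expect_lt(fe$exponential$sse, fe$linear$sse)
  fl <- fit_mass_growth(t, 2 + 0.01 * t)
  expect_equal(fl$preferred, "linear")
  expect_lt(fl$linear$sse, 1e-12)
  fc <- fit_mass_growth(t, rep(5, length(t)))
  expect_equal(fc$preferred, "linear")   # tie resolves to linear
  expect_lt(abs(fc$linear$slope), 1e-12)
  expect_lt(abs(fc$exponential$rate), 1e-8)
  expect_error(fit_mass_growth(t, c(-1, rep(2, length(t) - 1))), "positive")
})

test_that("model selection is reliable at 2% noise and rates are recovered", {
  # each series spans one cell cycle over which mass doubles, sampled every
  # 5 min, with 2% multiplicative measurement noise
  set.seed(20)
  correct <- 0
  k_errs <- c()
  for (i in 1:50) {
    expo <- i <= 25
    Tc <- runif(1, 120, 180)
    t <- seq(0, Tc, by = 5)
    m0 <- runif(1, 15, 25)
    if (expo) {
      k <- log(2) / Tc
      m <- m0 * exp(k * t)
    } else {
      m <- m0 * (1 + t / Tc)
    }
    m <- m * (1 + rnorm(length(t), 0, 0.02))
    f <- fit_mass_growth(t, m)
    if ((f$preferred == "exponential") == expo) correct <- correct + 1
    if (expo) k_errs <- c(k_errs, abs(f$exponential$rate / k - 1))
  }
  expect_gte(correct / 50, 0.95)
  expect_lt(mean(k_errs), 0.05)
})

test_that("stage percent changes reproduce the worked integer percentages", {
  expect_equal(stage_percent_change(c(267, 245))$percent_change, -8L)
  expect_equal(stage_percent_change(c(270, 288))$percent_change, 7L)
  expect_equal(stage_percent_change(c(264, 278))$percent_change, 5L)
  expect_error(stage_percent_change(c(0, 100)), "positive")
  # integer arithmetic: rounding half away from zero
  expect_equal(stage_percent_change(c(200, 203))$percent_change, 2L)
  expect_equal(stage_percent_change(c(200, 197))$percent_change, -2L)
})

sim_lineage <- function(swell, n_frames = 16) {
  # constant mass isolates the pure swell effect on density
  tl <- timelapse_spec(interval_min = 5, n_frames = n_frames, cycle_min = 150,
                       swell_fraction = swell, mass_rate = 0, seed = 2)
  cells <- list(seed_cell(center = c(16, 8), length = 12, age = 120))
  sim <- simulate_timelapse(tl, cells, phantom_grid(nx = 340, ny = 150),
                            render = "none")
  build_lineage(truth_records(sim$truth))
}

test_that("separation changes follow mass conservation", {
  sep5 <- separation_event_change(sim_lineage(0.05))
  expect_equal(sep5$dvolume_pct, 5, tolerance = 0.01)
  expect_equal(sep5$ddensity_pct, -100 * (1 - 1 / 1.05), tolerance = 0.01)
  expect_equal(round_half_away(sep5$ddensity_pct), -5)
  sep0 <- separation_event_change(sim_lineage(0))
  expect_lt(abs(sep0$dvolume_pct), 0.01)
  expect_lt(abs(sep0$ddensity_pct), 0.01)
  sep10 <- separation_event_change(sim_lineage(0.10))
  expect_equal(sep10$ddensity_pct, -100 * (1 - 1 / 1.10), tolerance = 0.01)
  # conservation identity drho/rho = -dV/(V+dV) to 0.1%
  expect_equal(sep10$ddensity_pct / 100,
               -(sep10$dvolume_pct / 100) / (1 + sep10$dvolume_pct / 100),
               tolerance = 1e-3)
})

test_that("homeostasis correlation detects corrective feedback", {
  set.seed(9)
  birth <- rnorm(100, 267, 10)
  delta <- -0.5 * (birth - 267) + rnorm(100, 0, 2)
  h <- density_homeostasis(birth, delta)
  expect_lt(h$r, 0)
  expect_lt(h$p_value, 1e-6)
  # null: independent changes
  h0 <- density_homeostasis(rnorm(100, 267, 10), rnorm(100, 0, 5))
  expect_gt(h0$p_value, 0.05)
  # perfect anticorrelation
  b <- seq(250, 280, length.out = 20)
  expect_equal(density_homeostasis(b, -b)$r, -1, tolerance = 1e-12)
  expect_error(density_homeostasis(rep(1, 20), rnorm(20)), "variance")
})

test_that("tip growth asymmetry pairs old/new ends via the inherited marker", {
  mk_cell <- function(old_growth, new_growth, rho_old, rho_new, y = 0) {
    nf <- 20
    # end A at x = 0 grows left (old), end B at x = 10 is the new end
    tip_a <- cbind(-seq(0, old_growth, length.out = nf), rep(y, nf))
    tip_b <- cbind(10 + seq(0, new_growth, length.out = nf), rep(y, nf))
    list(tip_a = tip_a, tip_b = tip_b,
         pole_a = rep(rho_old, nf), pole_b = rep(rho_new, nf),
         marker = c(10, y))   # division site at birth: next to end B
  }
  set.seed(4)
  cells <- lapply(1:12, function(i)
    mk_cell(4 + rnorm(1, 0, 0.3), 2 + rnorm(1, 0, 0.3),
            260 + rnorm(1, 0, 2), 275 + rnorm(1, 0, 2)))
  res <- tip_growth_asymmetry(cells)
  expect_equal(nrow(res$table), 12L)
  expect_gt(mean(res$paired$delta_elongation), 1.5)   # old grows ~2 um more
  expect_lt(mean(res$paired$delta_density), 0)        # old end less dense
  expect_lt(res$correlation, 0)                       # growth vs density
  # symmetric growth, uniform density: paired differences vanish
  sym <- lapply(1:5, function(i) mk_cell(3, 3, 270, 270))
  rs <- tip_growth_asymmetry(sym)
  expect_lt(max(abs(rs$paired$delta_elongation)), 1e-9)
  expect_lt(max(abs(rs$paired$delta_density)), 1e-9)
  # monopolar cell: new-end elongation is zero
  mono <- tip_growth_asymmetry(list(mk_cell(4, 0, 260, 275)))
  expect_lt(mono$table$new_elongation, 0.1075)
})

test_that("mass couples to area or volume as constructed", {
  t <- seq(0, 1, length.out = 30)
  # length and width both vary so area and volume are not collinear
  L <- 8 + 6 * t; r <- 1.7 + 0.3 * t
  V <- pi * r^2 * (L - 2 * r) + 4 / 3 * pi * r^3
  A <- 2 * pi * r * (L - 2 * r) + 4 * pi * r^2
  septum <- ifelse(t > 0.8, 2 * pi * r^2, 0)
  set.seed(12)
  jitter_m <- function(m) m * (1 + rnorm(length(m), 0, 1e-3))
  # mass proportional to area: area beats volume
  ra <- mass_area_volume_coupling(
    data.frame(cell = 1, mass_pg = jitter_m(0.2 * A), volume_fl = V,
               surface_area_um2 = A))
  expect_gt(ra$r2_area, ra$r2_volume)
  # mass tracking area incl. both septum faces: the augmented area wins
  rs <- mass_area_volume_coupling(
    data.frame(cell = 1, mass_pg = jitter_m(0.2 * (A + septum)), volume_fl = V,
               surface_area_um2 = A, septum_area_um2 = septum))
  expect_gt(rs$r2_area_septum, rs$r2_area)
  d_vol <- data.frame(cell = 1, mass_pg = jitter_m(0.27 * V), volume_fl = V,
                      surface_area_um2 = A)
  rv <- mass_area_volume_coupling(d_vol)
  expect_gt(rv$r2_volume, rv$r2_area)
})

test_that("septum concordance counts bent-away fractions", {
  mk <- function(cell, sag, rhoA, rhoB)
    data.frame(cell = cell, frame = 1, sagitta = sag, rho_A = rhoA, rho_B = rhoB)
  # all bowed away from the denser compartment (A denser, bowed toward B)
  allaway <- do.call(rbind, lapply(1:10, function(i) mk(i, 0.4, 300, 260)))
  expect_equal(bend_density_concordance(allaway)$fraction_concordant, 1.0)
  # all flat: concordance not applicable
  flat <- do.call(rbind, lapply(1:5, function(i) mk(i, 0.05, 280, 276)))
  rf <- bend_density_concordance(flat)
  expect_equal(rf$n_bent, 0L)
  expect_true(is.na(rf$fraction_concordant))
  # 64 bent (2 discordant) + 26 flat: 62/64 concordant
  mixed <- rbind(
    do.call(rbind, lapply(1:62, function(i) mk(i, 0.4, 300, 255))),
    do.call(rbind, lapply(63:64, function(i) mk(i, -0.4, 300, 286))),
    do.call(rbind, lapply(65:90, function(i) mk(i, 0.02, 286, 274))))
  rm_ <- bend_density_concordance(mixed)
  expect_equal(rm_$n_bent, 64L)
  expect_equal(rm_$n_concordant, 62L)
  expect_equal(rm_$fraction_concordant, 62 / 64, tolerance = 1e-12)
  expect_gt(rm_$mean_abs_diff_pct_bent, rm_$mean_abs_diff_pct_flat)
})
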