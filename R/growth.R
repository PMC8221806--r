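#' Exponential-vs-linear mass growth fit
#'
#' Fits `m(t) = a + b t` by ordinary least squares and `m(t) = m0 exp(k t)`
#' by nonlinear least squares (initialized from the log-linear fit), compares
#' the sums of squared residuals on the original scale (both models have two
#' parameters, so the raw SSE comparison is fair; AIC is reported as well),
#' and reports the preferred model. Ties resolve to linear (logged).
#'
#' @param time time points, min.
#' @param mass dry mass, pg; must be positive.
#' @return object of class `growth_fit`: list with `linear` (intercept,
#'   slope, sse, aic), `exponential` (m0, rate, sse, aic), `preferred`,
#'   `residuals` (data.frame), `exp_fallback` flag.
#' @export
fit_mass_growth <- function(time, mass) {
  stopifnot(length(time) == length(mass), length(mass) >= 6)
  if (any(mass <= 0)) stop("mass values must be positive")
  n <- length(mass)
  lf <- stats::lm(mass ~ time)
  sse_lin <- sum(stats::residuals(lf)^2)
  ll <- stats::lm(log(mass) ~ time)
  start <- list(m0 = exp(stats::coef(ll)[[1]]), k = stats::coef(ll)[[2]])
  fallback <- FALSE
  ef <- tryCatch(
    minpack.lm::nlsLM(mass ~ m0 * exp(k * time), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(ef)) {
    qc_log("exponential fit did not converge; log-linear fallback used")
    fallback <- TRUE
    m0 <- start$m0; k <- start$k
    pred <- m0 * exp(k * time)
  } else {
    m0 <- stats::coef(ef)[["m0"]]; k <- stats::coef(ef)[["k"]]
    pred <- stats::fitted(ef)
  }
  sse_exp <- sum((mass - pred)^2)
  aic <- function(sse) n * log(sse / n) + 2 * 2
  preferred <- if (sse_exp < sse_lin) "exponential" else "linear"
  if (sse_exp == sse_lin) qc_log("SSE tie; preferring linear")
  structure(list(
    linear = list(intercept = stats::coef(lf)[[1]], slope = stats::coef(lf)[[2]],
                  sse = sse_lin, aic = aic(sse_lin)),
    exponential = list(m0 = m0, rate = k, sse = sse_exp, aic = aic(sse_exp)),
    preferred = preferred,
    residuals = data.frame(time = time, linear = mass - stats::fitted(lf),
                           exponential = mass - pred),
    exp_fallback = fallback), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> preferred: %s | linear SSE %.4g | exponential SSE %.4g (k = %.5g /min)\n",
              x$preferred, x$linear$sse, x$exponential$sse, x$exponential$rate))
  invisible(x)
}

#' Percent density change over a cell-cycle stage
#'
#' Integer percent change between the stage's start and end densities,
#' rounded half away from zero (matching integer-percent reporting).
#'
#' @param density density series, mg/mL, or a length-2 vector of start/end
#'   values.
#' @param window `c(start, end)` indices into `density`; ignored for a
#'   length-2 input.
#' @param stage stage label.
#' @param interval_min frame interval for the duration, min.
#' @return object of class `stage_summary`: list with `stage`, `start`,
#'   `end`, `percent_change` (integer), `duration_min`.
#' @export
stage_percent_change <- function(density, window = NULL, stage = "stage",
                                 interval_min = NA_real_) {
  if (is.null(window)) {
    stopifnot(length(density) == 2)
    window <- c(1L, 2L)
  }
  stopifnot(window[1] >= 1, window[2] <= length(density), window[1] < window[2])
  start <- density[window[1]]; end <- density[window[2]]
  if (start <= 0) stop("start density must be positive")
  pct <- as.integer(round_half_away(100 * (end - start) / start))
  structure(list(stage = stage, start = start, end = end,
                 percent_change = pct,
                 duration_min = (window[2] - window[1]) * interval_min),
            class = "stage_summary")
}

#' @export
print.stage_summary <- function(x, ...) {
  cat(sprintf("<stage_summary> %s: %.0f -> %.0f mg/mL (%+d%%)\n",
              x$stage, x$start, x$end, x$percent_change))
  invisible(x)
}

#' Volume and density changes across separation events
#'
#' For each division with both daughters measured on their birth frame:
#' `dV% = 100 (sum V_daughters - V_mother) / V_mother` and
#' `drho% = 100 (mass-weighted mean daughter density - rho_mother) /
#' rho_mother` (an unweighted daughter mean is also reported).
#'
#' @param lin a `lineage` from [build_lineage()].
#' @return data.frame, one row per usable division: `parent`, `birth_frame`,
#'   `dvolume_pct`, `ddensity_pct`, `ddensity_unweighted_pct`.
#' @export
separation_event_change <- function(lin) {
  stopifnot(inherits(lin, "lineage"))
  out <- list()
  for (i in seq_len(nrow(lin$divisions))) {
    dv <- lin$divisions[i, ]
    mother <- lin$measurements[lin$measurements$track == dv$parent, , drop = FALSE]
    mother <- mother[which.max(mother$frame), , drop = FALSE]
    d1 <- lin$measurements[lin$measurements$track == dv$daughter1 &
                             lin$measurements$frame == dv$birth_frame, , drop = FALSE]
    d2 <- lin$measurements[lin$measurements$track == dv$daughter2 &
                             lin$measurements$frame == dv$birth_frame, , drop = FALSE]
    if (nrow(d1) != 1 || nrow(d2) != 1) {
      qc_log("division of track %d missing a daughter at birth; excluded", dv$parent)
      next
    }
    Vd <- d1$volume_fl + d2$volume_fl
    mw <- (d1$mass_pg * d1$density_mg_ml + d2$mass_pg * d2$density_mg_ml) /
      (d1$mass_pg + d2$mass_pg)
    uw <- (d1$density_mg_ml + d2$density_mg_ml) / 2
    out[[length(out) + 1]] <- data.frame(
      parent = dv$parent, birth_frame = dv$birth_frame,
      dvolume_pct = 100 * (Vd - mother$volume_fl) / mother$volume_fl,
      ddensity_pct = 100 * (mw - mother$density_mg_ml) / mother$density_mg_ml,
      ddensity_unweighted_pct = 100 * (uw - mother$density_mg_ml) / mother$density_mg_ml)
  }
  if (!length(out))
    return(data.frame(parent = integer(), birth_frame = integer(),
                      dvolume_pct = numeric(), ddensity_pct = numeric(),
                      ddensity_unweighted_pct = numeric()))
  do.call(rbind, out)
}

#' Density homeostasis correlation
#'
#' Pearson correlation (with regression slope and two-sided p) between
#' per-cell birth density and the density change over the cycle. A negative
#' correlation indicates corrective (homeostatic) regulation.
#'
#' @param birth_density per-cell density at birth, mg/mL.
#' @param delta_density per-cell change over the cycle, mg/mL.
#' @return object of class `homeostasis_result`: list with `r`, `slope`,
#'   `p_value`, `n`, and the input pairs.
#' @export
density_homeostasis <- function(birth_density, delta_density) {
  stopifnot(length(birth_density) == length(delta_density),
            length(birth_density) >= 10)
  if (stats::sd(birth_density) == 0 || stats::sd(delta_density) == 0)
    stop("zero variance in homeostasis inputs")
  ct <- stats::cor.test(birth_density, delta_density)
  slope <- stats::coef(stats::lm(delta_density ~ birth_density))[[2]]
  structure(list(r = unname(ct$estimate), slope = slope,
                 p_value = ct$p.value, n = length(birth_density),
                 pairs = data.frame(birth_density, delta_density)),
            class = "homeostasis_result")
}

#' @export
print.homeostasis_result <- function(x, ...) {
  cat(sprintf("<homeostasis_result> r = %.3f (p = %.3g, n = %d), slope = %.3f\n",
              x$r, x$p_value, x$n, x$slope))
  invisible(x)
}

#' Tip growth and polar density asymmetry
#'
#' Attributes elongation and cycle-mean polar density to the old and new end
#' of each cell. Ends are oriented by a fiduciary marker: the inherited
#' division-site coordinate (the end nearer the marker at birth is the new
#' end). Reports per-cell paired differences and the correlation between
#' per-end elongation and per-end mean density.
#'
#' @param cells list with one entry per cell: a list with `tip_a` / `tip_b`
#'   (2-column matrices of tip positions over the cycle, µm), `pole_a` /
#'   `pole_b` (polar density series, mg/mL), and `marker` (division-site
#'   coordinate at birth, length-2, µm).
#' @return list with `table` (per cell: old/new elongation and density) and
#'   `correlation` (Pearson r between end elongation and end density over
#'   all ends), `paired` (old - new differences).
#' @export
tip_growth_asymmetry <- function(cells) {
  rows <- list()
  for (ci in seq_along(cells)) {
    cl <- cells[[ci]]
    da <- sqrt(sum((cl$tip_a[1, ] - cl$marker)^2))
    db <- sqrt(sum((cl$tip_b[1, ] - cl$marker)^2))
    if (!is.finite(da) || !is.finite(db)) {
      qc_log("cell %d: marker unusable; excluded", ci)
      next
    }
    # the end nearer the inherited division site is the new end
    new_is_a <- da <= db
    el <- function(tips) sqrt(sum((tips[nrow(tips), ] - tips[1, ])^2))
    elong_a <- el(cl$tip_a); elong_b <- el(cl$tip_b)
    dens_a <- mean(cl$pole_a, na.rm = TRUE); dens_b <- mean(cl$pole_b, na.rm = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      cell = ci,
      old_elongation = if (new_is_a) elong_b else elong_a,
      new_elongation = if (new_is_a) elong_a else elong_b,
      old_density = if (new_is_a) dens_b else dens_a,
      new_density = if (new_is_a) dens_a else dens_b)
  }
  tab <- do.call(rbind, rows)
  ends <- data.frame(
    elongation = c(tab$old_elongation, tab$new_elongation),
    density = c(tab$old_density, tab$new_density))
  r <- if (stats::sd(ends$elongation) > 0 && stats::sd(ends$density) > 0)
    stats::cor(ends$elongation, ends$density) else NA_real_
  list(table = tab,
       paired = data.frame(delta_elongation = tab$old_elongation - tab$new_elongation,
                           delta_density = tab$old_density - tab$new_density),
       correlation = r)
}

#' Mass coupling to surface area versus volume
#'
#' Per-cell R-squared of mass against volume, against surface area, and
#' against surface area augmented by both faces of the septum disk
#' (`area + 2 pi r^2` during septation).
#'
#' @param traj data.frame per cell with columns `cell`, `mass_pg`,
#'   `volume_fl`, `surface_area_um2` and optionally `septum_area_um2` (the
#'   2 x disk-area term, 0 when no septum).
#' @return data.frame per cell: `r2_volume`, `r2_area`, `r2_area_septum`.
#' @export
mass_area_volume_coupling <- function(traj) {
  r2 <- function(y, x) summary(stats::lm(y ~ x))$r.squared
  cells <- unique(traj$cell)
  out <- lapply(cells, function(cid) {
    d <- traj[traj$cell == cid, , drop = FALSE]
    sep <- if ("septum_area_um2" %in% names(d)) d$septum_area_um2 else 0
    data.frame(cell = cid,
               r2_volume = r2(d$mass_pg, d$volume_fl),
               r2_area = r2(d$mass_pg, d$surface_area_um2),
               r2_area_septum = r2(d$mass_pg, d$surface_area_um2 + sep))
  })
  do.call(rbind, out)
}

#' Septum bend / density-difference concordance
#'
#' For each cell, the frame of maximum |compartment density difference| is
#' selected; the septum there is classified bent or flat by the sagitta
#' threshold, and a bent septum is concordant when it bows away from the
#' denser compartment (positive sagitta points toward pole B).
#'
#' @param septa data.frame with one row per cell per frame: `cell`, `frame`,
#'   `sagitta` (signed µm, positive toward pole B), `rho_A`, `rho_B`.
#' @param flat_sagitta |sagitta| below this is flat, µm.
#' @return object of class `concordance_result`: `n_total`, `n_bent`,
#'   `n_flat`, `n_concordant`, `fraction_concordant` (NA when no septum is
#'   bent), `mean_abs_diff_pct_bent`, `mean_abs_diff_pct_flat`.
#' @export
bend_density_concordance <- function(septa, flat_sagitta = 0.15) {
  cells <- unique(septa$cell)
  bent <- 0L; flat <- 0L; conc <- 0L
  diffs_bent <- c(); diffs_flat <- c()
  for (cid in cells) {
    d <- septa[septa$cell == cid & is.finite(septa$rho_A) & is.finite(septa$rho_B), ,
               drop = FALSE]
    if (!nrow(d)) next
    i <- which.max(abs(d$rho_A - d$rho_B))
    row <- d[i, ]
    diff_pct <- 100 * abs(row$rho_A - row$rho_B) /
      mean(c(row$rho_A, row$rho_B))
    if (abs(row$sagitta) < flat_sagitta) {
      flat <- flat + 1L
      diffs_flat <- c(diffs_flat, diff_pct)
    } else {
      bent <- bent + 1L
      diffs_bent <- c(diffs_bent, diff_pct)
      # bowed away from the denser compartment: sagitta points toward B when
      # A is denser, and toward A when B is denser
      away <- (row$sagitta > 0 && row$rho_A > row$rho_B) ||
        (row$sagitta < 0 && row$rho_B > row$rho_A)
      if (away) conc <- conc + 1L
    }
  }
  structure(list(n_total = bent + flat, n_bent = bent, n_flat = flat,
                 n_concordant = conc,
                 fraction_concordant = if (bent > 0) conc / bent else NA_real_,
                 mean_abs_diff_pct_bent = if (bent) mean(diffs_bent) else NA_real_,
                 mean_abs_diff_pct_flat = if (flat) mean(diffs_flat) else NA_real_),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance_result> %d/%d bent septa concordant (%.1f%%); %d flat\n",
              x$n_concordant, x$n_bent,
              100 * ifelse(is.na(x$fraction_concordant), 0, x$fraction_concordant),
              x$n_flat))
  invisible(x)
}
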