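#' Link cell records between consecutive frames
#'
#' Greedy nearest-center matching with the distance/area rule: a record at
#' frame t+1 continues a cell from frame t iff the centers are within
#' `max_dist_px` pixels (the rule's native unit; ~2 µm) and the new
#' cross-sectional area exceeds `min_area_frac` of the previous area.
#' Candidate pairs are scanned in order of increasing center distance;
#' distance ties are resolved toward the smaller area change (logged).
#'
#' @param records_t,records_t1 data.frames of cell measurements (columns
#'   `centroid_x`, `centroid_y`, `area_um2`, `label`) for frames t and t+1.
#' @param pixel_size µm; used to convert the pixel rule when the pixel size
#'   differs from the reference 0.1075 µm (20 px ~ 2 µm).
#' @param max_dist_px center distance threshold, pixels.
#' @param min_area_frac minimum area ratio area(t+1) / area(t).
#' @return integer vector over rows of `records_t`: matching row in
#'   `records_t1` or `NA`.
#' @export
link_frames <- function(records_t, records_t1, pixel_size = 0.1075,
                        max_dist_px = 20, min_area_frac = 0.70) {
  n0 <- nrow(records_t); n1 <- nrow(records_t1)
  if (n0 == 0 || n1 == 0) return(rep(NA_integer_, n0))
  max_dist_um <- max_dist_px * 0.1075
  if (abs(pixel_size - 0.1075) > 1e-9) max_dist_um <- 2.0
  d <- outer(records_t$centroid_x, records_t1$centroid_x, `-`)^2 +
    outer(records_t$centroid_y, records_t1$centroid_y, `-`)^2
  d <- sqrt(d)
  ratio <- outer(1 / records_t$area_um2, records_t1$area_um2)
  ok <- d <= max_dist_um & ratio > min_area_frac
  assign <- rep(NA_integer_, n0)
  taken <- rep(FALSE, n1)
  ord <- order(d)
  for (k in ord) {
    i <- (k - 1) %% n0 + 1
    j <- (k - 1) %/% n0 + 1
    if (!ok[k] || !is.na(assign[i]) || taken[j]) next
    # distance tie: prefer the smaller area change
    tie <- which(abs(d[i, ] - d[i, j]) < 1e-9 & ok[i, ] & !taken)
    if (length(tie) > 1) {
      j2 <- tie[which.min(abs(ratio[i, tie] - 1))]
      if (j2 != j) qc_log("distance tie at record %d resolved by area change", i)
      j <- j2
    }
    assign[i] <- j
    taken[j] <- TRUE
  }
  assign
}

#' Build a lineage from per-frame measurements
#'
#' Iterates [link_frames()] across frames to form tracks, then resolves each
#' track termination against tracks that begin on the following frame: a
#' division is called when exactly two new tracks start inside the parent's
#' final bounding box (dilated by `bbox_dilate_px` pixels) and their summed
#' area is within `area_sum_range` of the parent's; otherwise the track ends
#' `"lost"` (or `"censored"` at the field edge). The birth frame is the first
#' frame on which the daughters appear as separate components.
#'
#' @param measurements data.frame of cell measurements with a `frame` column
#'   (as from [measure_frame()], rbind-ed over frames).
#' @param pixel_size µm.
#' @param max_dist_px,min_area_frac linking thresholds (see [link_frames()]).
#' @param bbox_dilate_px parent bounding-box dilation for daughter matching.
#' @param area_sum_range admissible daughter area sum relative to the parent.
#' @param field_um optional `c(width, height)` of the field, µm; tracks whose
#'   final bounding box touches the field edge end `"censored"` instead of
#'   `"lost"`.
#' @return object of class `lineage`: list with `measurements` (the input
#'   plus `track` column), `tracks` (per-track table: track, start/end frame,
#'   parent, termination), `divisions` (parent, daughter tracks, birth frame).
#' @export
build_lineage <- function(measurements, pixel_size = 0.1075,
                          max_dist_px = 20, min_area_frac = 0.70,
                          bbox_dilate_px = 10, area_sum_range = c(0.8, 1.2),
                          field_um = NULL) {
  stopifnot(nrow(measurements) > 0)
  ms <- measurements[order(measurements$frame), , drop = FALSE]
  frames <- sort(unique(ms$frame))
  ms$track <- NA_integer_
  rows_by_frame <- split(seq_len(nrow(ms)), ms$frame)
  next_track <- 1L
  f1 <- as.character(frames[1])
  ms$track[rows_by_frame[[f1]]] <- seq_len(length(rows_by_frame[[f1]]))
  next_track <- length(rows_by_frame[[f1]]) + 1L
  for (fi in seq_along(frames)[-1]) {
    prev_rows <- rows_by_frame[[as.character(frames[fi - 1])]]
    cur_rows <- rows_by_frame[[as.character(frames[fi])]]
    asg <- link_frames(ms[prev_rows, , drop = FALSE],
                       ms[cur_rows, , drop = FALSE], pixel_size,
                       max_dist_px, min_area_frac)
    for (i in seq_along(asg)) {
      if (!is.na(asg[i]))
        ms$track[cur_rows[asg[i]]] <- ms$track[prev_rows[i]]
    }
    new <- which(is.na(ms$track[cur_rows]))
    for (j in new) {
      ms$track[cur_rows[j]] <- next_track
      next_track <- next_track + 1L
    }
  }
  # per-track summary
  tr_ids <- sort(unique(ms$track))
  tracks <- data.frame(track = tr_ids,
                       start_frame = vapply(tr_ids, function(t) min(ms$frame[ms$track == t]), 0),
                       end_frame = vapply(tr_ids, function(t) max(ms$frame[ms$track == t]), 0),
                       parent = NA_integer_,
                       termination = NA_character_)
  dil_um <- bbox_dilate_px * pixel_size
  divisions <- list()
  for (ti in seq_len(nrow(tracks))) {
    tend <- tracks$end_frame[ti]
    if (tend == max(frames)) { tracks$termination[ti] <- "censored"; next }
    fnext <- frames[which(frames == tend) + 1]
    last <- ms[ms$track == tracks$track[ti] & ms$frame == tend, , drop = FALSE]
    starters <- tracks$track[tracks$start_frame == fnext]
    cand <- ms[ms$track %in% starters & ms$frame == fnext, , drop = FALSE]
    if (nrow(cand) >= 2) {
      inside <- cand$centroid_x >= last$bbox_xmin - dil_um &
        cand$centroid_x <= last$bbox_xmax + dil_um &
        cand$centroid_y >= last$bbox_ymin - dil_um &
        cand$centroid_y <= last$bbox_ymax + dil_um
      cand <- cand[inside, , drop = FALSE]
    }
    if (nrow(cand) >= 2) {
      if (nrow(cand) > 2) {
        # choose the pair whose area sum best matches the parent
        cmb <- utils::combn(nrow(cand), 2)
        sums <- cand$area_um2[cmb[1, ]] + cand$area_um2[cmb[2, ]]
        best <- which.min(abs(sums / last$area_um2 - 1))
        qc_log("%d candidate daughters for track %d; best pair kept",
               nrow(cand), tracks$track[ti])
        cand <- cand[cmb[, best], , drop = FALSE]
      }
      frac <- sum(cand$area_um2) / last$area_um2
      if (frac >= area_sum_range[1] && frac <= area_sum_range[2]) {
        tracks$termination[ti] <- "division"
        dts <- cand$track
        tracks$parent[tracks$track %in% dts] <- tracks$track[ti]
        divisions[[length(divisions) + 1]] <- data.frame(
          parent = tracks$track[ti], daughter1 = dts[1], daughter2 = dts[2],
          birth_frame = fnext)
        next
      }
    }
    # tracks ending at the field edge are censored rather than lost
    at_edge <- !is.null(field_um) &&
      (last$bbox_xmin < dil_um || last$bbox_ymin < dil_um ||
         last$bbox_xmax > field_um[1] - dil_um ||
         last$bbox_ymax > field_um[2] - dil_um)
    tracks$termination[ti] <- if (at_edge) "censored" else "lost"
    if (!at_edge)
      qc_log("track %d lost after frame %d", tracks$track[ti], tend)
  }
  structure(list(measurements = ms, tracks = tracks,
                 divisions = if (length(divisions)) do.call(rbind, divisions)
                 else data.frame(parent = integer(), daughter1 = integer(),
                                 daughter2 = integer(), birth_frame = integer())),
            class = "lineage")
}

#' @export
print.lineage <- function(x, ...) {
  cat(sprintf("<lineage> %d tracks, %d divisions over frames %d..%d\n",
              nrow(x$tracks), nrow(x$divisions),
              min(x$measurements$frame), max(x$measurements$frame)))
  invisible(x)
}

#' Align a birth-to-division track to normalized cell-cycle time
#'
#' Resamples a complete track's volume, density and mass onto a normalized
#' time grid by linear interpolation, with t = 0 at birth and t = 1 at the
#' last frame before separation. Endpoint values are preserved exactly.
#'
#' @param track_ms data.frame of the track's measurements, ordered by frame
#'   (columns `volume_fl`, `density_mg_ml`, `mass_pg`).
#' @param grid_points number of normalized time points.
#' @param min_frames tracks shorter than this are rejected.
#' @return data.frame with `t` (0..1), `volume_fl`, `density_mg_ml`,
#'   `mass_pg`.
#' @export
align_to_cycle <- function(track_ms, grid_points = 100, min_frames = 5) {
  n <- nrow(track_ms)
  if (n < min_frames) {
    qc_log("track with %d frames excluded from alignment (min %d)", n, min_frames)
    return(NULL)
  }
  t_in <- (track_ms$frame - track_ms$frame[1]) /
    (track_ms$frame[n] - track_ms$frame[1])
  tg <- seq(0, 1, length.out = grid_points)
  data.frame(
    t = tg,
    volume_fl = stats::approx(t_in, track_ms$volume_fl, tg)$y,
    density_mg_ml = stats::approx(t_in, track_ms$density_mg_ml, tg)$y,
    mass_pg = stats::approx(t_in, track_ms$mass_pg, tg)$y)
}

#' Population mean/SD trajectories over the normalized cycle
#'
#' @param lin a `lineage`.
#' @param grid_points normalized grid size.
#' @param min_frames minimum frames for a track to contribute.
#' @return data.frame: `t`, then mean/sd/n for volume, density and mass.
#'   Only complete birth-to-division tracks (born by a detected division and
#'   terminated by one) contribute.
#' @export
population_trajectories <- function(lin, grid_points = 100, min_frames = 5) {
  stopifnot(inherits(lin, "lineage"))
  complete <- lin$tracks$track[!is.na(lin$tracks$parent) &
                                 lin$tracks$termination == "division"]
  parts <- list()
  for (t in complete) {
    tm <- lin$measurements[lin$measurements$track == t, , drop = FALSE]
    tm <- tm[order(tm$frame), , drop = FALSE]
    al <- align_to_cycle(tm, grid_points, min_frames)
    if (!is.null(al)) { al$track <- t; parts[[length(parts) + 1]] <- al }
  }
  if (!length(parts)) return(NULL)
  allal <- do.call(rbind, parts)
  agg <- function(v) {
    m <- tapply(allal[[v]], allal$t, mean)
    s <- tapply(allal[[v]], allal$t, stats::sd)
    data.frame(mean = as.vector(m), sd = as.vector(s))
  }
  tg <- sort(unique(allal$t))
  out <- data.frame(t = tg,
                    volume_mean = agg("volume_fl")$mean,
                    volume_sd = agg("volume_fl")$sd,
                    density_mean = agg("density_mg_ml")$mean,
                    density_sd = agg("density_mg_ml")$sd,
                    mass_mean = agg("mass_pg")$mean,
                    mass_sd = agg("mass_pg")$sd)
  attr(out, "n_tracks") <- length(parts)
  out
}
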