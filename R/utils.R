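# Angular spatial frequencies (rad/µm) for an n-point grid with spacing d (µm),
# in FFT order.
fft_freq <- function(n, d) {
  f <- c(seq(0L, floor((n - 1) / 2)), seq(-ceiling((n - 1) / 2), -1L)) / (n * d)
  2 * pi * f
}

# Mirror-pad a matrix by `pad` pixels on every side (reflection without
# repeating the edge sample would need pad < dim; reflection with edge repeat
# is fine for our purposes).
mirror_pad <- function(m, pad) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(min(pad, nr))), seq_len(nr), nr + 1 - seq_len(min(pad, nr)))
  ci <- c(rev(seq_len(min(pad, nc))), seq_len(nc), nc + 1 - seq_len(min(pad, nc)))
  m[ri, ci, drop = FALSE]
}

crop_pad <- function(m, pad, nr, nc) {
  m[pad + seq_len(nr), pad + seq_len(nc), drop = FALSE]
}

# Round half away from zero (integer-percent reporting convention).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

# Distance from points (px, py) to the segment a--b (all in µm, 2-D).
dist_to_segment <- function(px, py, a, b) {
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  L2 <- vx^2 + vy^2
  if (L2 == 0) return(sqrt((px - a[1])^2 + (py - a[2])^2))
  t <- ((px - a[1]) * vx + (py - a[2]) * vy) / L2
  t <- pmin(1, pmax(0, t))
  sqrt((px - a[1] - t * vx)^2 + (py - a[2] - t * vy)^2)
}

qc_log <- function(...) {
  if (isTRUE(getOption("qpicell.verbose", FALSE))) message(sprintf(...))
  invisible(NULL)
}
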