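# Shared fixtures, built in code.

# Quiet phantom: no noise, no pulse, static arc. Good for exact model checks.
quiet_spec <- function(...) {
  phantom_spec(noise_sd = 0, pulse_amplitude = 0, growth_rate = 0,
               rng_seed = 42L, ...)
}

# Small volume with a bright cuboid on a uniform background.
block_volume <- function(n = 20L, bg = 1000, hi = 3000, n_frames = 3L,
                         shifts = rep(0L, n_frames), core = 6:10) {
  frames <- lapply(shifts, function(s) {
    a <- array(bg, c(n, n, n))
    a[core + s, core, core] <- hi
    a
  })
  volume_series(frames, spacing = 1, dt = 10)
}

# Spherical-shell volume with a radial Gaussian intensity profile peaking at
# mid-radius r_peak (physical um), used for ray-casting tests.
shell_volume <- function(n = 41L, sp = 2, r_peak = 32, width = 3,
                         amplitude = 5000, n_frames = 2L) {
  cen <- (c(n, n, n) + 1) / 2
  g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  r <- sqrt(((g$z - cen[1]) * sp)^2 + ((g$y - cen[2]) * sp)^2 +
              ((g$x - cen[3]) * sp)^2)
  a <- array(amplitude * exp(-0.5 * ((r - r_peak) / width)^2), c(n, n, n))
  volume_series(rep(list(a), n_frames), spacing = sp, dt = 10)
}

# Hand-built phase kymograph for wave-number unit tests: one side only is
# exercised; `phi_fun(row_distance_px, col)` gives the wrapped phase.
toy_phase_kymograph <- function(n_side = 30L, n_t = 4L,
                                phi_fun = function(d, j) 0,
                                spatial_pixel = 2.088, dt = 10) {
  n_rows <- 2L * n_side + 1L
  mid <- n_side + 1L
  mat <- matrix(0, n_rows, n_t)
  for (j in seq_len(n_t)) {
    for (r in seq_len(n_rows)) {
      mat[r, j] <- phi_fun(abs(r - mid), j)
    }
  }
  structure(
    list(mat = mat, period = matrix(150, n_rows, n_t),
         power = matrix(1, n_rows, n_t),
         valid = matrix(TRUE, n_rows, n_t), onset_frame = 1L,
         spatial_pixel = spatial_pixel, dt = dt, midline_row = mid,
         start_time = 0),
    class = "phase_kymograph"
  )
}

# Tracks with a prescribed distance-to-path profile: the reference path is
# the x axis from 0 to 600 um; distance from the path is then simply |y|
# (points kept at z = 0 within the x span).
line_path <- function() {
  build_surface_path(c(0, 0, 0), c(0, 0, 300), c(0, 0, 600),
                     n_segments = 1000L)
}

distance_track <- function(id, dist_um, dt = 10) {
  n <- length(dist_um)
  data.frame(track_id = id, t_min = (seq_len(n) - 1) * dt,
             x_um = 300, y_um = dist_um, z_um = 0)
}
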