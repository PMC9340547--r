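#' Phantom embryo specification
#'
#' Parameters of the synthetic oscillatory-tissue phantom: an egg-cylinder
#' shell (hemispherical cap on a cylinder) expressing an oscillatory reporter
#' whose period varies linearly in arc distance along the proximo-distal
#' surface arc, preceded by a quasi-synchronous tissue-wide pulse. The wave
#' origin sits at the cap apex; the two distal ends sit on the cylinder rim
#' on the left (+y) and right (-y) meridians. The oscillation phase is
#' `phi(s, t) = 2*pi*t / P(s)` with `P` linear in the relative arc position
#' `s / L(t)`, so that `phi(s, 0) = 0` everywhere and the wave number grows
#' as `q(t) = t * (1/P_prox - 1/P_dist)`.
#'
#' Default periods match the measured proximal/distal medians (133 and
#' 153 min); default tissue growth and advection speeds sit in the reported
#' 0.1-0.3 um/min mesoderm motility range.
#'
#' @param proximal_period,distal_period oscillation period (min) at the wave
#'   origin and at the distal end of the arc.
#' @param pulse_peak_time time (min) of the pulse peak; the default places it
#'   260 min before the first frame, i.e. waves start at `t = 0`.
#' @param pulse_width Gaussian temporal sd of the pulse (min).
#' @param pulse_amplitude,oscillation_amplitude,background_level intensity
#'   model amplitudes (counts).
#' @param noise_sd additive Gaussian intensity noise sd (counts), clipped at 0.
#' @param shell_radius,shell_thickness,cylinder_height shell geometry (um);
#'   the mid-surface radius is `shell_radius - shell_thickness/2`.
#' @param initial_arc_length arc length (um) at `t = 0` for the direct
#'   kymograph phantom (the 3D phantom derives it from the geometry).
#' @param growth_rate linear arc-length growth (um/min).
#' @param advection_speed cell advection speed along the surface (um/min);
#'   `NULL` draws one speed per track uniformly from `speed_range`.
#' @param speed_range range (um/min) speeds are drawn from when
#'   `advection_speed` is `NULL`.
#' @param voxel_spacing isotropic voxel spacing (um).
#' @param frame_interval_dt frame interval (min).
#' @param n_frames number of frames (>= 2).
#' @param rng_seed integer seed; identical specs give bit-identical phantoms.
#' @param period_range admissible period range (min) for validation.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(proximal_period = 133,
                         distal_period = 153,
                         pulse_peak_time = -260,
                         pulse_width = 75,
                         pulse_amplitude = 400,
                         oscillation_amplitude = 200,
                         background_level = 1100,
                         noise_sd = 20,
                         shell_radius = 90,
                         shell_thickness = 20,
                         cylinder_height = 60,
                         initial_arc_length = 300,
                         growth_rate = 0.2,
                         advection_speed = NULL,
                         speed_range = c(0.1, 0.3),
                         voxel_spacing = 2.088,
                         frame_interval_dt = 10,
                         n_frames = 100,
                         rng_seed = 1L,
                         period_range = c(40, 400)) {
  spec <- list(
    proximal_period = proximal_period, distal_period = distal_period,
    pulse_peak_time = pulse_peak_time, pulse_width = pulse_width,
    pulse_amplitude = pulse_amplitude,
    oscillation_amplitude = oscillation_amplitude,
    background_level = background_level, noise_sd = noise_sd,
    shell_radius = shell_radius, shell_thickness = shell_thickness,
    cylinder_height = cylinder_height,
    initial_arc_length = initial_arc_length, growth_rate = growth_rate,
    advection_speed = advection_speed, speed_range = speed_range,
    voxel_spacing = voxel_spacing, frame_interval_dt = frame_interval_dt,
    n_frames = as.integer(n_frames), rng_seed = as.integer(rng_seed),
    period_range = period_range
  )
  if (any(c(proximal_period, distal_period) < period_range[1]) ||
      any(c(proximal_period, distal_period) > period_range[2])) {
    stop("periods must lie within period_range [", period_range[1], ", ",
         period_range[2], "] min")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (frame_interval_dt <= 0) stop("frame_interval_dt must be > 0")
  if (shell_thickness >= shell_radius) {
    stop("shell_thickness must be smaller than shell_radius")
  }
  if (spec$n_frames < 2L) stop("n_frames must be >= 2")
  if (voxel_spacing <= 0) stop("voxel_spacing must be > 0")
  if (pulse_width <= 0) stop("pulse_width must be > 0")
  if (any(c(pulse_amplitude, oscillation_amplitude, background_level) < 0)) {
    stop("amplitudes and background must be >= 0")
  }
  structure(spec, class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>\n")
  cat(sprintf("  periods: %g (proximal) -> %g (distal) min, dt = %g min, %d frames\n",
              x$proximal_period, x$distal_period, x$frame_interval_dt, x$n_frames))
  cat(sprintf("  shell: radius %g um, thickness %g um, cylinder %g um, growth %g um/min\n",
              x$shell_radius, x$shell_thickness, x$cylinder_height, x$growth_rate))
  cat(sprintf("  amplitudes: background %g, oscillation %g, pulse %g, noise sd %g\n",
              x$background_level, x$oscillation_amplitude, x$pulse_amplitude,
              x$noise_sd))
  invisible(x)
}

# Mid-surface radius of the shell.
mid_radius <- function(spec) spec$shell_radius - spec$shell_thickness / 2

# Closure factories: built at top level so the returned functions capture
# only their arguments, not a generator frame holding full volumes.
make_shell_arc_len <- function(spec) {
  cap_arc <- mid_radius(spec) * pi / 2
  function(t) cap_arc + cyl_height(spec, t)
}

make_linear_arc_len <- function(l0, rate) {
  force(l0); force(rate)
  function(t) l0 + rate * t
}

make_shell_landmarks_fn <- function(spec, center) {
  force(center)
  rm <- mid_radius(spec)
  function(t) {
    h <- cyl_height(spec, t)
    list(origin = c(center[1] - rm, center[2], center[3]),
         left_distal = c(center[1] + h, center[2] + rm, center[3]),
         right_distal = c(center[1] + h, center[2] - rm, center[3]))
  }
}

# Cylinder height at time t (linear growth).
cyl_height <- function(spec, t) spec$cylinder_height + spec$growth_rate * t

# Ground truth carried by every generator.
phantom_truth <- function(spec, arc_length_fn, landmarks_fn = NULL,
                          track_velocities = NULL) {
  pp <- spec$proximal_period; pd <- spec$distal_period
  period <- function(s, t = 0) {
    sigma <- pmin(pmax(s / arc_length_fn(t), 0), 1)
    pp + (pd - pp) * sigma
  }
  structure(
    list(
      spec = spec,
      arc_length = arc_length_fn,
      period = period,
      phase = function(s, t) 2 * pi * t / period(s, t),
      q = function(t) t * (1 / pp - 1 / pd),
      landmarks = landmarks_fn,
      track_velocities = track_velocities
    ),
    class = "phantom_truth"
  )
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth> analytic phase/period/q of a linear-gradient phantom\n")
  cat(sprintf("  P(0) = %g min, P(L) = %g min, L(0) = %g um\n",
              x$period(0, 0), x$period(x$arc_length(0), 0), x$arc_length(0)))
  invisible(x)
}

# Map (arc distance s from the apex, azimuth) to a physical (z,y,x) point on
# the mid-surface. center is the cap center (z,y,x um).
surface_point <- function(s, azimuth, center, rm) {
  cap_arc <- rm * pi / 2
  on_cap <- s <= cap_arc
  alpha <- pmin(s, cap_arc) / rm
  r_lat <- rm * sin(alpha)
  dz <- ifelse(on_cap, -rm * cos(alpha), s - cap_arc)
  cbind(center[1] + dz,
        center[2] + r_lat * sin(azimuth),
        center[3] + r_lat * cos(azimuth))
}

# Inverse of surface_point for points near the mid-surface: returns the arc
# distance from the apex along the point's meridian, measured at the
# mid-surface radius rm.
shell_arc_coord <- function(pts, center, rm) {
  dz <- pts[, 1] - center[1]
  dy <- pts[, 2] - center[2]
  dx <- pts[, 3] - center[3]
  r_lat <- sqrt(dy^2 + dx^2)
  ifelse(dz <= 0,
         rm * atan2(r_lat, -dz),  # cap: polar angle from the apex
         rm * pi / 2 + dz)        # cylinder: quarter arc + axial distance
}

# Landmark keyframes of the phantom (exact, linear in t): apex origin plus
# left/right distal rim points.
phantom_landmarks <- function(spec, center) {
  rm <- mid_radius(spec)
  times <- (seq_len(spec$n_frames) - 1L) * spec$frame_interval_dt
  keys <- range(times)
  lm_at <- function(t) {
    h <- cyl_height(spec, t)
    list(origin = c(center[1] - rm, center[2], center[3]),
         left_distal = c(center[1] + h, center[2] + rm, center[3]),
         right_distal = c(center[1] + h, center[2] - rm, center[3]))
  }
  landmark_set(
    times = keys,
    origin = do.call(rbind, lapply(keys, function(t) lm_at(t)$origin)),
    left_distal = do.call(rbind, lapply(keys, function(t) lm_at(t)$left_distal)),
    right_distal = do.call(rbind, lapply(keys, function(t) lm_at(t)$right_distal)),
    rotation_angles = c(0, 0, 0)
  )
}

#' Generate a 3D+t phantom embryo volume
#'
#' Renders the egg-cylinder shell phantom into a 16-bit-range volume series:
#' shell voxels carry `background + pulse(t) + A*(1 + cos(phi(s, t)))/2` plus
#' optional Gaussian noise; everything outside the shell is air (0 counts
#' plus noise). Landmark keyframes (apex origin, left/right distal rim
#' points, rotation angles) and the analytic ground truth are returned
#' alongside.
#'
#' @param spec a [phantom_spec()].
#' @param vol_dim integer volume dimensions `(z, y, x)` in voxels, or `NULL`
#'   to auto-size the volume around the shell.
#' @param margin_um clearance (um) between shell and volume faces.
#' @return a list with elements `volume` ([volume_series()]), `landmarks`
#'   ([landmark_set()]) and `truth` (`phantom_truth`).
#' @export
generate_phantom_volume <- function(spec, vol_dim = NULL, margin_um = 25) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$voxel_spacing
  rm <- mid_radius(spec)
  times <- (seq_len(spec$n_frames) - 1L) * spec$frame_interval_dt
  h_final <- cyl_height(spec, max(times))
  if (is.null(vol_dim)) {
    nz <- ceiling((2 * margin_um + spec$shell_radius + h_final) / sp) + 1
    nxy <- ceiling((2 * margin_um + 2 * spec$shell_radius) / sp) + 1
    vol_dim <- c(nz, nxy, nxy)
  }
  vol_dim <- as.integer(vol_dim)
  extent <- (vol_dim - 1) * sp
  if (extent[1] < 2 * margin_um + spec$shell_radius + h_final ||
      any(extent[2:3] < 2 * spec$shell_radius + 2 * margin_um)) {
    stop(sprintf(
      paste0("volume of %dx%dx%d voxels at %g um spacing cannot contain the ",
             "shell (radius %g um, final cylinder height %g um, margin %g um)"),
      vol_dim[1], vol_dim[2], vol_dim[3], sp, spec$shell_radius, h_final,
      margin_um))
  }
  center <- c(margin_um + spec$shell_radius,
              extent[2] / 2, extent[3] / 2)

  # per-voxel static geometry (z,y,x physical coordinates)
  zc <- (seq_len(vol_dim[1]) - 1) * sp - center[1]
  yc <- (seq_len(vol_dim[2]) - 1) * sp - center[2]
  xc <- (seq_len(vol_dim[3]) - 1) * sp - center[3]
  dz <- array(zc, dim = vol_dim)
  dy <- array(rep(yc, each = vol_dim[1]), dim = vol_dim)
  dx <- array(rep(xc, each = vol_dim[1] * vol_dim[2]), dim = vol_dim)
  r_lat2 <- dy^2 + dx^2
  rho_cap <- sqrt(dz^2 + r_lat2)
  r_lat <- sqrt(r_lat2)
  in_cap_z <- dz <= 0
  rho <- ifelse(in_cap_z, rho_cap, r_lat)
  shell_radial <- rho >= spec$shell_radius - spec$shell_thickness &
    rho <= spec$shell_radius
  s_arc <- ifelse(in_cap_z, rm * atan2(r_lat, -dz), rm * pi / 2 + dz)

  cap_arc <- rm * pi / 2
  pp <- spec$proximal_period; pdist <- spec$distal_period
  frames <- with_seed(spec$rng_seed, {
    lapply(times, function(t) {
      h <- cyl_height(spec, t)
      ltot <- cap_arc + h
      shell <- shell_radial & (in_cap_z | dz <= h)
      sigma <- pmin(pmax(s_arc / ltot, 0), 1)
      period <- pp + (pdist - pp) * sigma
      phi <- 2 * pi * t / period
      pulse <- spec$pulse_amplitude *
        exp(-0.5 * ((t - spec$pulse_peak_time) / spec$pulse_width)^2)
      f <- array(0, dim = vol_dim)
      f[shell] <- spec$background_level + pulse +
        spec$oscillation_amplitude * (1 + cos(phi[shell])) / 2
      if (spec$noise_sd > 0) {
        f <- f + array(stats::rnorm(length(f), 0, spec$noise_sd), dim = vol_dim)
      }
      f[f < 0] <- 0
      f[f > 65535] <- 65535
      f
    })
  })
  vol <- volume_series(frames, spacing = sp, dt = spec$frame_interval_dt)
  truth <- phantom_truth(spec, make_shell_arc_len(spec),
                         landmarks_fn = make_shell_landmarks_fn(spec, center))
  truth$center <- center
  list(volume = vol, landmarks = phantom_landmarks(spec, center), truth = truth)
}

#' Generate a phantom kymograph directly
#'
#' Fast-path surrogate for the full 3D chain: renders the 1D arc intensity
#' model straight into a midline-centered two-sided kymograph. The arc grows
#' as `initial_arc_length + growth_rate * t`; rows beyond the current arc
#' length carry the fill value and are masked invalid.
#'
#' @param spec a [phantom_spec()].
#' @param fill fill value (counts) for out-of-domain cells.
#' @param n_side_rows rows per side, or `NULL` to size for the final arc
#'   length plus a small margin.
#' @param spatial_pixel kymograph pixel size in um (defaults to the voxel
#'   spacing).
#' @return list with elements `kymo` ([kymograph()]) and `truth`.
#' @export
generate_phantom_kymograph <- function(spec, fill = 1067, n_side_rows = NULL,
                                       spatial_pixel = spec$voxel_spacing) {
  stopifnot(inherits(spec, "phantom_spec"))
  times <- (seq_len(spec$n_frames) - 1L) * spec$frame_interval_dt
  arc_len <- make_linear_arc_len(spec$initial_arc_length, spec$growth_rate)
  l_max <- arc_len(max(times))
  if (is.null(n_side_rows)) n_side_rows <- floor(l_max / spatial_pixel) + 3L
  if (n_side_rows * spatial_pixel < l_max) {
    stop(sprintf(
      "arc grows to %.1f um but the kymograph holds only %d rows (%.1f um) per side",
      l_max, n_side_rows, n_side_rows * spatial_pixel))
  }
  n_rows <- 2L * n_side_rows + 1L
  midline <- n_side_rows + 1L
  s_row <- abs(seq_len(n_rows) - midline) * spatial_pixel
  pp <- spec$proximal_period; pdist <- spec$distal_period
  mat <- matrix(fill, nrow = n_rows, ncol = length(times))
  valid <- matrix(FALSE, nrow = n_rows, ncol = length(times))
  with_seed(spec$rng_seed + 1L, {
    for (j in seq_along(times)) {
      t <- times[j]
      l <- arc_len(t)
      ok <- s_row <= l
      sigma <- pmin(s_row[ok] / l, 1)
      period <- pp + (pdist - pp) * sigma
      phi <- 2 * pi * t / period
      pulse <- spec$pulse_amplitude *
        exp(-0.5 * ((t - spec$pulse_peak_time) / spec$pulse_width)^2)
      v <- spec$background_level + pulse +
        spec$oscillation_amplitude * (1 + cos(phi)) / 2
      if (spec$noise_sd > 0) v <- pmax(0, v + stats::rnorm(length(v), 0, spec$noise_sd))
      mat[ok, j] <- v
      valid[, j] <- ok
    }
  })
  km <- kymograph(mat, spatial_pixel = spatial_pixel,
                  dt = spec$frame_interval_dt, midline_row = midline,
                  valid = valid, fill = fill)
  list(kymo = km, truth = phantom_truth(spec, arc_len))
}

#' Analytic surface paths of a phantom
#'
#' Builds the per-frame left/right lines of interest of a phantom directly
#' from its ground truth (origin at the cap apex, intermediate point at half
#' the arc, distal end on the rim), bypassing volume-based landmark
#' localization. Used for track filtering and for tests that need exact
#' paths.
#'
#' @param truth a `phantom_truth` with a `center` element.
#' @param times frame times in minutes.
#' @param n_segments chord segments per path.
#' @return list with `left` and `right` lists of [build_surface_path()]s
#'   (one per time).
#' @export
phantom_paths <- function(truth, times, n_segments = 100000L) {
  stopifnot(inherits(truth, "phantom_truth"), !is.null(truth$center))
  rm <- mid_radius(truth$spec)
  center <- truth$center
  one_side <- function(azimuth) {
    lapply(times, function(t) {
      l <- truth$arc_length(t)
      p <- surface_point(c(0, l / 2, l), azimuth, center, rm)
      build_surface_path(p[1, ], p[2, ], p[3, ], n_segments = n_segments)
    })
  }
  list(left = one_side(pi / 2), right = one_side(-pi / 2))
}

#' Generate phantom cell tracks
#'
#' Tracks are seeded near the wave origin (cap apex) and advected away along
#' shell meridians at constant per-track speed, with optional isotropic
#' positional jitter, sampled uniformly at the frame interval.
#'
#' @param spec a [phantom_spec()].
#' @param n_tracks number of tracks.
#' @param jitter_sd isotropic positional jitter sd (um).
#' @param seed_arc_max tracks start within this arc distance (um) of the
#'   origin.
#' @return list with elements `tracks` (data.frame with columns `track_id`,
#'   `t_min`, `x_um`, `y_um`, `z_um`) and `truth` (per-track speeds in
#'   `truth$track_velocities`).
#' @export
generate_phantom_tracks <- function(spec, n_tracks = 50, jitter_sd = 0.5,
                                    seed_arc_max = 30) {
  stopifnot(inherits(spec, "phantom_spec"))
  rm <- mid_radius(spec)
  times <- (seq_len(spec$n_frames) - 1L) * spec$frame_interval_dt
  center <- c(spec$shell_radius + 25, 0, 0)  # same layout as the 3D phantom
  res <- with_seed(spec$rng_seed + 2L, {
    s0 <- stats::runif(n_tracks, 0, seed_arc_max)
    az <- stats::runif(n_tracks, 0, 2 * pi)
    v <- if (is.null(spec$advection_speed)) {
      stats::runif(n_tracks, spec$speed_range[1], spec$speed_range[2])
    } else rep(spec$advection_speed, n_tracks)
    rows <- lapply(seq_len(n_tracks), function(i) {
      s <- s0[i] + v[i] * times
      p <- surface_point(s, az[i], center, rm)
      if (jitter_sd > 0) {
        p <- p + matrix(stats::rnorm(length(p), 0, jitter_sd), ncol = 3L)
      }
      data.frame(track_id = i, t_min = times,
                 x_um = p[, 3], y_um = p[, 2], z_um = p[, 1])
    })
    list(tracks = do.call(rbind, rows), v = v)
  })
  truth <- phantom_truth(spec, make_shell_arc_len(spec),
                         track_velocities = res$v)
  truth$center <- center
  list(tracks = res$tracks, truth = truth)
}
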