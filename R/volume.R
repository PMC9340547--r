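#' 3D+t intensity volume series
#'
#' Container for a single-channel time series of 3D intensity volumes with
#' physical voxel spacing and frame interval. Frames are stored as a list of
#' 3D arrays in `(z, y, x)` order; the proximodistal axis of an aligned
#' embryo runs along `z` and the anteroposterior axis along `y`. Physical
#' coordinates are voxel index minus one times spacing, i.e. the first voxel
#' center sits at the origin.
#'
#' @param frames list of 3D numeric arrays, all with the same dimensions.
#' @param spacing numeric length-3 voxel spacing `(z, y, x)` in micrometers.
#' @param dt frame interval in minutes.
#' @param start_time acquisition time of the first frame in minutes.
#' @return an object of class `volume_series`.
#' @export
volume_series <- function(frames, spacing, dt, start_time = 0) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  d <- dim(frames[[1]])
  if (length(d) != 3L) stop("frames must be 3D arrays (z, y, x)")
  for (f in frames) {
    if (!identical(dim(f), d)) stop("all frames must share one shape")
    if (any(f < 0)) stop("intensities must be >= 0")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be 3 positive values (z, y, x)")
  }
  if (dt <= 0) stop("frame interval dt must be > 0")
  structure(
    list(frames = frames, spacing = spacing, dt = as.numeric(dt),
         start_time = as.numeric(start_time)),
    class = "volume_series"
  )
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<volume_series> %d frames of %dx%dx%d (z,y,x) voxels\n", length(x$frames),
    d[1], d[2], d[3]))
  cat(sprintf("  spacing (z,y,x): %.4g x %.4g x %.4g um, dt = %g min, t0 = %g min\n",
              x$spacing[1], x$spacing[2], x$spacing[3], x$dt, x$start_time))
  invisible(x)
}

#' @export
dim.volume_series <- function(x) c(length(x$frames), dim(x$frames[[1]]))

#' Frame acquisition times of a volume series
#'
#' @param vol a [volume_series()].
#' @return numeric vector of frame times in minutes.
#' @export
frame_times <- function(vol) {
  vol$start_time + (seq_along(vol$frames) - 1L) * vol$dt
}

# Physical (z,y,x) coordinate of the volume center, in micrometers.
volume_center <- function(vol) (dim(vol$frames[[1]]) - 1) / 2 * vol$spacing

# Convert physical (z,y,x) points (rows) to fractional 1-based voxel indices.
phys_to_voxel <- function(pts, spacing) {
  sweep(pts, 2L, spacing, "/") + 1
}
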