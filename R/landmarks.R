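#' Landmark keyframe set
#'
#' Manually annotated keyframes of the wave origin and the left/right distal
#' ends, plus optional rotation angles and expression-domain bounding boxes.
#' Landmarks at intermediate frames are obtained by linear interpolation
#' ([interpolate_landmarks()]).
#'
#' @param times keyframe times in minutes, strictly increasing.
#' @param origin,left_distal,right_distal matrices (one row per keyframe) of
#'   `(z, y, x)` positions in micrometers.
#' @param rotation_angles optional global rotation angles (degrees, about the
#'   z, y, x axes) used for axis alignment.
#' @param bbox optional expression-domain bounding boxes, one row per
#'   keyframe: `(z_min, z_max, y_min, y_max, x_min, x_max)` in micrometers.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(times, origin, left_distal, right_distal,
                         rotation_angles = c(0, 0, 0), bbox = NULL) {
  times <- as.numeric(times)
  if (length(times) < 1L) stop("landmark set needs at least one keyframe")
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("keyframe times must be strictly increasing")
  }
  as_mat <- function(m, name) {
    m <- rbind(m)
    if (nrow(m) != length(times) || ncol(m) != 3L) {
      stop(name, " must have one (z, y, x) row per keyframe")
    }
    unname(m)
  }
  structure(
    list(times = times,
         origin = as_mat(origin, "origin"),
         left_distal = as_mat(left_distal, "left_distal"),
         right_distal = as_mat(right_distal, "right_distal"),
         rotation_angles = as.numeric(rotation_angles),
         bbox = if (!is.null(bbox)) unname(rbind(bbox)) else NULL),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d keyframe(s) at t = %s min\n",
              length(x$times), paste(signif(x$times, 4), collapse = ", ")))
  invisible(x)
}

#' Interpolate landmarks to arbitrary frame times
#'
#' Coordinate-wise linear interpolation between the bracketing keyframes;
#' outside the keyframe span the nearest keyframe value is held (clamped).
#'
#' @param lm a [landmark_set()].
#' @param frame_times times (min) to interpolate to.
#' @return list with matrices `origin`, `left_distal`, `right_distal`
#'   (one row per frame time) and the vector `times`.
#' @export
interpolate_landmarks <- function(lm, frame_times) {
  stopifnot(inherits(lm, "landmark_set"))
  interp <- function(m) {
    if (length(lm$times) == 1L) {
      return(matrix(rep(m[1L, ], each = length(frame_times)),
                    ncol = 3L))
    }
    vapply(1:3, function(d) {
      stats::approx(lm$times, m[, d], xout = frame_times, rule = 2)$y
    }, numeric(length(frame_times)))
  }
  out <- lapply(list(origin = lm$origin, left_distal = lm$left_distal,
                     right_distal = lm$right_distal), interp)
  out <- lapply(out, function(m) matrix(m, ncol = 3L))
  out$times <- as.numeric(frame_times)
  out
}

#' Locate the intermediate surface point by ray casting
#'
#' For each frame, the midpoint of the origin-distal pair is computed and
#' intensity is sampled along the ray from the embryo center of mass through
#' that midpoint out to the volume edge; the position of the intensity
#' maximum is recorded (ties resolved toward the center of mass). A cubic
#' smoothing spline over time replaces the raw per-frame maxima, suppressing
#' frame-to-frame jitter of the argmax.
#'
#' @param vol a [volume_series()].
#' @param com center of mass `(z, y, x)` in micrometers.
#' @param origin,distal matrices (frames x 3) of per-frame landmark
#'   positions in micrometers.
#' @param step ray sampling step in micrometers (default half the smallest
#'   voxel spacing).
#' @param spar smoothing parameter passed to [stats::smooth.spline()];
#'   `NULL` selects it by generalized cross-validation.
#' @return list with `points` (smoothed, frames x 3) and `raw` (per-frame
#'   argmax positions).
#' @export
locate_intermediate_point <- function(vol, com, origin, distal, step = NULL,
                                      spar = NULL) {
  stopifnot(inherits(vol, "volume_series"))
  com <- as.numeric(com)
  d <- dim(vol$frames[[1]])
  extent <- (d - 1) * vol$spacing
  if (is.null(step)) step <- min(vol$spacing) / 2
  n_t <- length(vol$frames)
  stopifnot(nrow(origin) == n_t, nrow(distal) == n_t)
  raw <- matrix(NA_real_, nrow = n_t, ncol = 3L)
  for (j in seq_len(n_t)) {
    mid <- (origin[j, ] + distal[j, ]) / 2
    dir <- mid - com
    nd <- sqrt(sum(dir^2))
    if (nd < 1e-9) {
      stop("degenerate geometry: center of mass coincides with the landmark midpoint")
    }
    dir <- dir / nd
    # distance to the volume boundary along the ray
    tmax <- Inf
    for (ax in 1:3) {
      if (dir[ax] > 0) tmax <- min(tmax, (extent[ax] - com[ax]) / dir[ax])
      if (dir[ax] < 0) tmax <- min(tmax, -com[ax] / dir[ax])
    }
    if (!is.finite(tmax) || tmax <= 0) {
      stop("ray from the center of mass exits the volume immediately")
    }
    ts <- seq(0, tmax, by = step)
    pts <- cbind(com[1] + ts * dir[1], com[2] + ts * dir[2],
                 com[3] + ts * dir[3])
    vals <- trilinear(vol$frames[[j]], phys_to_voxel(pts, vol$spacing),
                      fill = -Inf)
    # first maximum (ties to a relative tolerance) = closest to the COM
    mx <- max(vals)
    k <- which(vals >= mx - 1e-9 * max(1, abs(mx)))[1]
    raw[j, ] <- pts[k, ]
  }
  pts <- raw
  if (n_t >= 4L) {
    tt <- frame_times(vol)
    for (dd in 1:3) {
      fit <- if (is.null(spar)) stats::smooth.spline(tt, raw[, dd]) else
        stats::smooth.spline(tt, raw[, dd], spar = spar)
      pts[, dd] <- stats::predict(fit, tt)$y
    }
  }
  list(points = pts, raw = raw)
}
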