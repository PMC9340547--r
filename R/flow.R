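#' Validate a cell-track table
#'
#' Tracks are plain data.frames with columns `track_id`, `t_min`, `x_um`,
#' `y_um`, `z_um`; each track must have at least two samples at strictly
#' increasing, uniformly spaced times.
#'
#' @param tracks a data.frame of track samples.
#' @return the validated data.frame (invisibly usable as-is).
#' @export
validate_tracks <- function(tracks) {
  need <- c("track_id", "t_min", "x_um", "y_um", "z_um")
  if (!all(need %in% names(tracks))) {
    stop("tracks must have columns ", paste(need, collapse = ", "))
  }
  for (id in unique(tracks$track_id)) {
    tt <- tracks$t_min[tracks$track_id == id]
    if (length(tt) < 2L) stop("track ", id, " has fewer than 2 samples")
    d <- diff(tt)
    if (any(d <= 0) || diff(range(d)) > 1e-6 * max(d)) {
      stop("track ", id, " must have strictly increasing, uniformly spaced times")
    }
  }
  tracks
}

#' Align track clocks to the wave onset
#'
#' Shifts every timestamp so that `t = 0` falls a fixed interval after the
#' peak of the pre-oscillation pulse (260 min by default, the designated
#' start of waves).
#'
#' @param tracks track data.frame (see [validate_tracks()]).
#' @param pulse_peak_time time of the pulse peak on the tracks' clock (min).
#' @param onset_offset minutes between pulse peak and wave onset
#'   (default 260).
#' @return the tracks with shifted `t_min`.
#' @export
align_track_time <- function(tracks, pulse_peak_time, onset_offset = 260) {
  tracks$t_min <- tracks$t_min - (pulse_peak_time + onset_offset)
  tracks
}

#' Select tracks that follow the line of interest
#'
#' A track is kept when it contains a run of consecutive samples spanning at
#' least `min_consecutive_min` minutes in which every sample lies within
#' `radius_um` of the surface path of its frame. Tracks whose samples fall
#' outside the covered time span are excluded with a log message rather than
#' an error.
#'
#' @param tracks track data.frame.
#' @param paths list of per-frame [build_surface_path()] objects.
#' @param path_times frame times (min) of `paths`, on the tracks' clock.
#' @param radius_um proximity radius in micrometers (default 30).
#' @param min_consecutive_min minimal consecutive proximity span in minutes
#'   (default 300).
#' @param path_step_um spacing of the path points used for the distance
#'   computation (default 2 um).
#' @return the kept subset of `tracks`; kept ids in
#'   `attr(, "kept_ids")`, excluded-for-coverage ids in
#'   `attr(, "uncovered_ids")`.
#' @export
filter_tracks_by_path <- function(tracks, paths, path_times, radius_um = 30,
                                  min_consecutive_min = 300,
                                  path_step_um = 2) {
  validate_tracks(tracks)
  stopifnot(length(paths) == length(path_times))
  path_pts <- lapply(paths, function(p) {
    arc_lookup(p, seq(0, p$total_length, by = path_step_um))$points
  })
  kept <- logical(0)
  uncovered <- c()
  ids <- unique(tracks$track_id)
  keep_ids <- c()
  for (id in ids) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    fi <- match_frame(tr$t_min, path_times)
    if (anyNA(fi)) {
      uncovered <- c(uncovered, id)
      next
    }
    d <- vapply(seq_len(nrow(tr)), function(k) {
      pts <- path_pts[[fi[k]]]
      p <- c(tr$z_um[k], tr$y_um[k], tr$x_um[k])
      sqrt(min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 +
                 (pts[, 3] - p[3])^2))
    }, numeric(1))
    inside <- d <= radius_um
    if (longest_run_span(inside, tr$t_min) >= min_consecutive_min) {
      keep_ids <- c(keep_ids, id)
    }
  }
  if (length(uncovered)) {
    message("filter_tracks_by_path: ", length(uncovered),
            " track(s) outside the path time coverage were excluded")
  }
  out <- tracks[tracks$track_id %in% keep_ids, , drop = FALSE]
  attr(out, "kept_ids") <- keep_ids
  attr(out, "uncovered_ids") <- uncovered
  out
}

# Nearest path frame for each sample time; NA if no frame within half a step.
match_frame <- function(t, path_times) {
  i <- vapply(t, function(tt) which.min(abs(path_times - tt)), integer(1))
  tol <- if (length(path_times) > 1L) min(diff(sort(path_times))) / 2 else Inf
  ifelse(abs(path_times[i] - t) <= tol + 1e-9, i, NA_integer_)
}

# Longest time span (max(t) - min(t)) of a run of consecutive TRUE samples.
longest_run_span <- function(flag, t) {
  if (!any(flag)) return(0)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  spans <- ifelse(r$values, t[ends] - t[starts], 0)
  max(spans)
}

#' Average tracks into a vector field
#'
#' Finite-difference velocities (central differences in the interior,
#' one-sided at the ends) of the selected tracks are binned on a 2D grid
#' over the projected (arc distance along the path, signed lateral offset)
#' plane, using the wave origin and `t = 0` as the common reference; each
#' occupied cell carries the mean velocity vector and the sample count.
#'
#' @param tracks track data.frame (time-aligned and filtered).
#' @param path a reference [build_surface_path()] used for the projection.
#' @param cell_um grid cell size in micrometers (default 20).
#' @param path_step_um path sampling step for the projection (default 2 um).
#' @return object of class `vector_field`: data.frame with columns `s_um`,
#'   `lat_um` (cell centers), `vs`, `vlat` (mean in-plane velocity,
#'   um/min), `speed` (norm of the mean 3D velocity vector), `n` (samples).
#' @export
average_vector_field <- function(tracks, path, cell_um = 20,
                                 path_step_um = 2) {
  validate_tracks(tracks)
  if (nrow(tracks) == 0L) {
    warning("no tracks selected; returning an empty vector field")
    out <- data.frame(s_um = numeric(0), lat_um = numeric(0),
                      vs = numeric(0), vlat = numeric(0),
                      speed = numeric(0), n = integer(0))
    class(out) <- c("vector_field", "data.frame")
    return(out)
  }
  proj <- project_on_path(cbind(tracks$z_um, tracks$y_um, tracks$x_um),
                          path, path_step_um)
  # per-sample velocities
  v <- matrix(NA_real_, nrow(tracks), 3L)
  vs <- vlat <- rep(NA_real_, nrow(tracks))
  for (id in unique(tracks$track_id)) {
    sel <- which(tracks$track_id == id)
    tr <- tracks[sel, , drop = FALSE]
    p <- cbind(tr$z_um, tr$y_um, tr$x_um)
    v[sel, ] <- finite_diff(p, tr$t_min)
    vs[sel] <- finite_diff(cbind(proj$s[sel]), tr$t_min)
    vlat[sel] <- finite_diff(cbind(proj$lat[sel]), tr$t_min)
  }
  cs <- floor(proj$s / cell_um)
  cl <- floor(proj$lat / cell_um)
  key <- paste(cs, cl)
  agg <- function(x) as.numeric(tapply(x, key, mean))
  n <- as.integer(tapply(rep(1L, length(key)), key, sum))
  vx <- vapply(1:3, function(d) as.numeric(tapply(v[, d], key, mean)),
               numeric(length(n)))
  vx <- matrix(vx, ncol = 3L)
  out <- data.frame(
    s_um = (as.numeric(tapply(cs, key, mean)) + 0.5) * cell_um,
    lat_um = (as.numeric(tapply(cl, key, mean)) + 0.5) * cell_um,
    vs = agg(vs), vlat = agg(vlat),
    speed = sqrt(rowSums(vx^2)), n = n
  )
  class(out) <- c("vector_field", "data.frame")
  attr(out, "cell_um") <- cell_um
  out
}

#' @export
print.vector_field <- function(x, ...) {
  cat(sprintf("<vector_field> %d occupied cells, %d samples, mean speed %.3f um/min\n",
              nrow(x), sum(x$n), stats::weighted.mean(x$speed, x$n)))
  invisible(x)
}

# Project 3D points (rows, z/y/x um) onto (arc distance, signed lateral
# offset); the sign is taken along the normal of the anchor plane.
project_on_path <- function(pts, path, path_step_um = 2) {
  ss <- seq(0, path$total_length, by = path_step_um)
  cpts <- arc_lookup(path, ss)$points
  a <- path$anchors[2, ] - path$anchors[1, ]
  b <- path$anchors[3, ] - path$anchors[1, ]
  nrm <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
  nl <- sqrt(sum(nrm^2))
  nrm <- if (nl > 1e-9) nrm / nl else c(0, 0, 1)
  s <- lat <- numeric(nrow(pts))
  for (k in seq_len(nrow(pts))) {
    d2 <- (cpts[, 1] - pts[k, 1])^2 + (cpts[, 2] - pts[k, 2])^2 +
      (cpts[, 3] - pts[k, 3])^2
    i <- which.min(d2)
    s[k] <- ss[i]
    delta <- pts[k, ] - cpts[i, ]
    lat[k] <- sum(delta * nrm)
  }
  list(s = s, lat = lat)
}

# Finite-difference derivative of rows of p with respect to t: central in
# the interior, one-sided at the ends. Returns a matrix like p (or vector
# speed if p has 1 column).
finite_diff <- function(p, t) {
  n <- nrow(p)
  out <- matrix(NA_real_, n, ncol(p))
  if (n == 1L) return(out)
  for (d in seq_len(ncol(p))) {
    x <- p[, d]
    out[1, d] <- (x[2] - x[1]) / (t[2] - t[1])
    out[n, d] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
    if (n > 2L) {
      mid <- 2:(n - 1)
      out[mid, d] <- (x[mid + 1] - x[mid - 1]) / (t[mid + 1] - t[mid - 1])
    }
  }
  if (ncol(p) == 1L) out[, 1] else out
}

#' Streamlines of a vector field
#'
#' Integrates seed points through the bilinearly interpolated `(vs, vlat)`
#' field with fixed-step Euler integration; a visualization aid, not a
#' statistic.
#'
#' @param field a [average_vector_field()] result.
#' @param seeds matrix of seed points `(s_um, lat_um)`; defaults to the
#'   occupied cell centers.
#' @param step_min integration step in minutes (default 10).
#' @param n_steps number of steps (default 50).
#' @return data.frame with columns `streamline`, `step`, `s_um`, `lat_um`.
#' @export
field_streamlines <- function(field, seeds = NULL, step_min = 10,
                              n_steps = 50L) {
  stopifnot(inherits(field, "vector_field"))
  if (nrow(field) == 0L) {
    return(data.frame(streamline = integer(0), step = integer(0),
                      s_um = numeric(0), lat_um = numeric(0)))
  }
  if (is.null(seeds)) seeds <- cbind(field$s_um, field$lat_um)
  interp_v <- function(p) {
    d2 <- (field$s_um - p[1])^2 + (field$lat_um - p[2])^2
    w <- 1 / pmax(d2, 1e-6)
    c(sum(w * field$vs) / sum(w), sum(w * field$vlat) / sum(w))
  }
  out <- vector("list", nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    p <- seeds[i, ]
    pts <- matrix(NA_real_, n_steps + 1L, 2L)
    pts[1, ] <- p
    for (k in seq_len(n_steps)) {
      p <- p + step_min * interp_v(p)
      pts[k + 1L, ] <- p
    }
    out[[i]] <- data.frame(streamline = i, step = 0:n_steps,
                           s_um = pts[, 1], lat_um = pts[, 2])
  }
  do.call(rbind, out)
}
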