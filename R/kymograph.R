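#' Midline-centered kymograph
#'
#' Space-by-time matrix of intensity (or phase) sampled along the line of
#' interest. The proximal origin sits on the midline row; rows above the
#' midline (smaller row index, increasing distance) belong to the left arc,
#' rows below to the right arc. Cells outside the arc at a given time carry
#' the fill value and are masked invalid.
#'
#' @param mat numeric matrix, rows = spatial samples, columns = timepoints.
#' @param spatial_pixel spatial pixel size in micrometers (one row step).
#' @param dt frame interval in minutes.
#' @param midline_row row index of the proximal origin.
#' @param valid logical validity mask, same shape as `mat`; `NULL` marks all
#'   cells valid.
#' @param fill fill value stored in invalid cells.
#' @param start_time time of the first column in minutes.
#' @return an object of class `kymograph`.
#' @export
kymograph <- function(mat, spatial_pixel, dt, midline_row,
                      valid = NULL, fill = 1067, start_time = 0) {
  mat <- as.matrix(mat)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(mat), ncol(mat))
  stopifnot(identical(dim(valid), dim(mat)), spatial_pixel > 0, dt > 0,
            midline_row >= 1, midline_row <= nrow(mat))
  mat[!valid] <- fill
  structure(
    list(mat = mat, spatial_pixel = spatial_pixel, dt = dt,
         midline_row = as.integer(midline_row), valid = valid, fill = fill,
         start_time = as.numeric(start_time)),
    class = "kymograph"
  )
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d rows x %d timepoints, midline row %d\n",
              nrow(x$mat), ncol(x$mat), x$midline_row))
  cat(sprintf("  spatial pixel %.4g um, dt %g min, fill %g, %.1f%% valid\n",
              x$spatial_pixel, x$dt, x$fill, 100 * mean(x$valid)))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, ...) {
  img <- t(x$mat[rev(seq_len(nrow(x$mat))), , drop = FALSE])
  graphics::image(
    x = x$start_time + (seq_len(ncol(x$mat)) - 1) * x$dt,
    y = (seq_len(nrow(x$mat)) - x$midline_row) * x$spatial_pixel,
    z = img, xlab = "time (min)", ylab = "arc distance from origin (um)",
    col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

# Column times of a kymograph.
kymo_times <- function(km) km$start_time + (seq_len(ncol(km$mat)) - 1L) * km$dt

# Row indices of one side ordered from the midline outward.
side_rows <- function(km, side = c("left", "right")) {
  side <- match.arg(side)
  if (side == "left") seq(km$midline_row, 1L) else
    seq(km$midline_row, nrow(km$mat))
}

#' Sample a surface kymograph from a volume series
#'
#' The volume is pre-smoothed with a 3D Gaussian, then for every frame and
#' each side's surface path the intensity is averaged within a sphere
#' centered at each integer arc-distance step; the origin series is fixed at
#' the midline with the left arc extending above and the right arc below.
#' Spheres reaching outside the volume average over the in-bounds voxels
#' only (counted and reported via a message).
#'
#' @param vol a [volume_series()] with isotropic spacing.
#' @param left_paths,right_paths lists with one [build_surface_path()] per
#'   frame.
#' @param smoothing_sigma_px 3D Gaussian sigma in pixels (default 6, about
#'   12.5 um at 2.088 um spacing).
#' @param sphere_diameter_px sampling sphere diameter in pixels (default 12,
#'   about 25 um).
#' @param fill fill value for out-of-domain cells.
#' @return a [kymograph()]; the spatial pixel equals the voxel spacing.
#' @export
sample_surface_kymograph <- function(vol, left_paths, right_paths,
                                     smoothing_sigma_px = 6,
                                     sphere_diameter_px = 12, fill = 1067) {
  stopifnot(inherits(vol, "volume_series"))
  sp <- vol$spacing
  if (diff(range(sp)) > 1e-6 * mean(sp)) {
    stop("surface kymograph sampling requires an isotropic volume")
  }
  px <- sp[1]
  n_t <- length(vol$frames)
  stopifnot(length(left_paths) == n_t, length(right_paths) == n_t)
  r_px <- sphere_diameter_px / 2
  off <- as.matrix(expand.grid(z = -floor(r_px):floor(r_px),
                               y = -floor(r_px):floor(r_px),
                               x = -floor(r_px):floor(r_px)))
  off <- off[rowSums(off^2) <= r_px^2, , drop = FALSE]
  n_off <- nrow(off)
  n_side <- max(vapply(c(left_paths, right_paths),
                       function(p) floor(p$total_length / px), numeric(1)))
  n_rows <- 2L * n_side + 1L
  midline <- n_side + 1L
  mat <- matrix(fill, n_rows, n_t)
  valid <- matrix(FALSE, n_rows, n_t)
  d <- dim(vol$frames[[1]])
  n_partial <- 0L
  for (j in seq_len(n_t)) {
    f <- gaussian_smooth3(vol$frames[[j]], smoothing_sigma_px)
    for (side in c("left", "right")) {
      path <- if (side == "left") left_paths[[j]] else right_paths[[j]]
      ks <- 0:floor(path$total_length / px)
      pts <- arc_lookup(path, ks * px)$points
      vox <- round(phys_to_voxel(pts, sp))
      centers <- vox[rep(seq_len(nrow(vox)), each = n_off), , drop = FALSE] +
        off[rep(seq_len(n_off), times = nrow(vox)), , drop = FALSE]
      inb <- centers[, 1] >= 1 & centers[, 1] <= d[1] &
        centers[, 2] >= 1 & centers[, 2] <= d[2] &
        centers[, 3] >= 1 & centers[, 3] <= d[3]
      vals <- rep(NA_real_, nrow(centers))
      vals[inb] <- f[centers[inb, , drop = FALSE]]
      grp <- rep(seq_along(ks), each = n_off)
      sums <- rowsum(ifelse(inb, vals, 0), grp)
      cnts <- rowsum(as.numeric(inb), grp)
      means <- as.numeric(sums / pmax(cnts, 1))
      means[cnts == 0] <- fill
      n_partial <- n_partial + sum(cnts > 0 & cnts < n_off)
      rows <- if (side == "left") midline - ks else midline + ks
      mat[rows, j] <- means
      valid[rows, j] <- cnts > 0
    }
  }
  if (n_partial > 0L) {
    message(sprintf(
      "sample_surface_kymograph: %d sphere(s) extended outside the volume; partial means used",
      n_partial))
  }
  kymograph(mat, spatial_pixel = px, dt = vol$dt, midline_row = midline,
            valid = valid, fill = fill, start_time = vol$start_time)
}

#' Kymograph from maximum intensity projections
#'
#' Per frame, the volume is projected by maximum intensity along the chosen
#' axis, the projection is smoothed with a 2D Gaussian, and intensity is
#' averaged in a corridor of the given width perpendicular to the spline
#' path.
#'
#' @param vol a [volume_series()].
#' @param paths list with one [build_surface_path()] per frame; only the two
#'   in-plane coordinates of the path are used.
#' @param axis projection axis, `"y"` (image plane `(z, x)`) or `"z"`
#'   (image plane `(y, x)`).
#' @param corridor_um corridor width in micrometers (default 25).
#' @param gaussian_sigma_um 2D Gaussian sigma in micrometers (default 12).
#' @param fill fill value for out-of-domain cells.
#' @return a [kymograph()] with the origin at the first row's side of the
#'   path (single-sided: midline row 1).
#' @export
mip_kymograph <- function(vol, paths, axis = c("y", "z"), corridor_um = 25,
                          gaussian_sigma_um = 12, fill = 1067) {
  stopifnot(inherits(vol, "volume_series"))
  axis <- match.arg(axis)
  keep <- if (axis == "y") c(1L, 3L) else c(2L, 3L)
  margin <- if (axis == "y") 2L else 1L
  sp2 <- vol$spacing[keep]
  d2 <- dim(vol$frames[[1]])[keep]
  if (corridor_um > min((d2 - 1) * sp2)) {
    stop("corridor is wider than the projected image")
  }
  n_t <- length(vol$frames)
  stopifnot(length(paths) == n_t)
  px <- min(sp2)
  n_rows <- max(vapply(paths, function(p) floor(p$total_length / px),
                       numeric(1))) + 1L
  mat <- matrix(fill, n_rows, n_t)
  valid <- matrix(FALSE, n_rows, n_t)
  n_half <- max(1L, round(corridor_um / px / 2))
  offs <- (-n_half:n_half) * px
  for (j in seq_len(n_t)) {
    mip <- apply(vol$frames[[j]], keep, max)
    sig_px <- gaussian_sigma_um / sp2
    if (sig_px[1] > 0) {
      mip <- apply(mip, 2L, convolve_reflect, kernel = gaussian_kernel(sig_px[1]))
    }
    if (sig_px[2] > 0) {
      mip <- t(apply(mip, 1L, convolve_reflect, kernel = gaussian_kernel(sig_px[2])))
    }
    path <- paths[[j]]
    ks <- 0:floor(path$total_length / px)
    lk <- arc_lookup(path, ks * px)
    pts <- lk$points[, keep, drop = FALSE]
    # unit tangents in the projection plane, central differences
    tang <- apply(pts, 2L, function(v) c(diff(v)[1], diff(v)))
    tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
    nrm <- cbind(-tang[, 2], tang[, 1])
    acc <- matrix(0, length(ks), length(offs))
    for (oi in seq_along(offs)) {
      q <- pts + offs[oi] * nrm
      idx <- cbind(q[, 1] / sp2[1] + 1, q[, 2] / sp2[2] + 1)
      acc[, oi] <- bilinear(mip, idx, fill = NA)
    }
    v <- rowMeans(acc, na.rm = TRUE)
    v[is.nan(v)] <- fill
    mat[ks + 1L, j] <- v
    valid[ks + 1L, j] <- !is.nan(rowMeans(acc, na.rm = TRUE))
  }
  kymograph(mat, spatial_pixel = px, dt = vol$dt, midline_row = 1L,
            valid = valid, fill = fill, start_time = vol$start_time)
}

# Bilinear interpolation of a matrix at fractional 1-based indices.
bilinear <- function(m, idx, fill = NA) {
  d <- dim(m)
  i <- idx[, 1]; j <- idx[, 2]
  ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & is.finite(i) & is.finite(j)
  out <- rep(fill, nrow(idx))
  if (!any(ok)) return(out)
  i <- i[ok]; j <- j[ok]
  i0 <- pmin(pmax(floor(i), 1), max(d[1] - 1L, 1L)); fi <- i - i0
  j0 <- pmin(pmax(floor(j), 1), max(d[2] - 1L, 1L)); fj <- j - j0
  if (d[1] == 1L) fi <- 0
  if (d[2] == 1L) fj <- 0
  i1 <- pmin(i0 + 1L, d[1]); j1 <- pmin(j0 + 1L, d[2])
  out[ok] <- m[cbind(i0, j0)] * (1 - fi) * (1 - fj) +
    m[cbind(i1, j0)] * fi * (1 - fj) +
    m[cbind(i0, j1)] * (1 - fi) * fj +
    m[cbind(i1, j1)] * fi * fj
  out
}

#' Transverse optical section
#'
#' Maximum intensity projection over an axial (z) slab of the given
#' thickness, centered at a stated fraction of the proximodistal extent of
#' the expression domain.
#'
#' @param vol a [volume_series()].
#' @param frame frame index.
#' @param domain_z_range proximodistal extent `(z_min, z_max)` of the
#'   expression domain in micrometers (from the landmark annotation).
#' @param proximodistal_fraction position of the slab center within the
#'   domain extent, in `[0, 1]` (default 0.5).
#' @param slab_um slab thickness in micrometers (default 12).
#' @return 2D matrix `(y, x)`.
#' @export
transverse_section <- function(vol, frame, domain_z_range,
                               proximodistal_fraction = 0.5, slab_um = 12) {
  stopifnot(inherits(vol, "volume_series"))
  if (missing(domain_z_range) || is.null(domain_z_range)) {
    stop("domain annotation (domain_z_range) is required")
  }
  if (proximodistal_fraction < 0 || proximodistal_fraction > 1) {
    stop("proximodistal_fraction must lie in [0, 1]")
  }
  f <- vol$frames[[frame]]
  zc <- domain_z_range[1] +
    proximodistal_fraction * diff(range(domain_z_range))
  z_lo <- (zc - slab_um / 2) / vol$spacing[1] + 1
  z_hi <- (zc + slab_um / 2) / vol$spacing[1] + 1
  zi <- max(1L, ceiling(z_lo)):min(dim(f)[1], floor(z_hi))
  if (length(zi) < 1L) zi <- round((z_lo + z_hi) / 2)
  if (any(zi < 1L) || any(zi > dim(f)[1])) stop("slab does not fit in the volume")
  apply(f[zi, , , drop = FALSE], c(2L, 3L), max)
}

#' Normalize an intensity profile
#'
#' LOWESS smoothing with a fractional bandwidth, background subtraction
#' (minimum) and normalization to the maximum, mirroring the processing of
#' normalized intensity profiles; each step can be disabled for raw
#' pass-through plots.
#'
#' @param profile numeric vector (length >= 3).
#' @param lowess_bandwidth LOWESS fraction `f` (default 0.06); `NA` or 0
#'   skips smoothing.
#' @param subtract_background subtract the profile minimum.
#' @param normalize_max divide by the maximum after background subtraction.
#' @return numeric vector of the same length.
#' @export
normalize_profile <- function(profile, lowess_bandwidth = 0.06,
                              subtract_background = TRUE,
                              normalize_max = TRUE) {
  if (length(profile) < 3L) stop("profile must have length >= 3")
  y <- as.numeric(profile)
  if (!is.na(lowess_bandwidth) && lowess_bandwidth > 0) {
    y <- stats::lowess(seq_along(y), y, f = lowess_bandwidth, iter = 0L)$y
  }
  if (subtract_background) y <- y - min(y)
  if (normalize_max) {
    m <- max(y)
    if (m <= 0) {
      warning("profile is constant; normalization undefined, returning zeros")
      return(rep(0, length(y)))
    }
    y <- y / m
  }
  y
}

#' Line profiles from a kymograph
#'
#' Extracts a temporal profile at a fixed arc distance (averaging a stripe
#' of rows, default 10 px, about 14 um on typical projections) or a spatial
#' profile at a fixed timepoint (averaging a stripe of columns).
#'
#' @param km a [kymograph()].
#' @param along `"time"` (profile over columns at one row) or `"space"`.
#' @param index center row (for `"time"`) or column (for `"space"`).
#' @param stripe_px stripe width averaged over (default 10).
#' @return numeric profile; cells without any valid stripe member are `NA`.
#' @export
kymo_profile <- function(km, along = c("time", "space"), index,
                         stripe_px = 10L) {
  stopifnot(inherits(km, "kymograph"))
  along <- match.arg(along)
  offs <- seq_len(stripe_px) - 1L - floor((stripe_px - 1L) / 2)
  if (along == "time") {
    rows <- index + offs
    rows <- rows[rows >= 1L & rows <= nrow(km$mat)]
    vapply(seq_len(ncol(km$mat)), function(j) {
      r <- rows[km$valid[rows, j]]
      if (length(r) == 0L) NA_real_ else mean(km$mat[r, j])
    }, numeric(1))
  } else {
    cols <- index + offs
    cols <- cols[cols >= 1L & cols <= ncol(km$mat)]
    vapply(seq_len(nrow(km$mat)), function(r) {
      cc <- cols[km$valid[r, cols]]
      if (length(cc) == 0L) NA_real_ else mean(km$mat[r, cc])
    }, numeric(1))
  }
}
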