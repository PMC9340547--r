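#' Default temporal-background box
#'
#' Corner box used for temporal background estimation: 30 x 30 voxels in
#' (y, x) and up to 150 voxels in z, clipped to the volume. The caller must
#' ensure the corner lies outside the specimen.
#'
#' @param vol a [volume_series()].
#' @return integer vector `(z1, z2, y1, y2, x1, x2)` of 1-based inclusive
#'   voxel bounds.
#' @export
default_background_box <- function(vol) {
  d <- dim(vol$frames[[1]])
  c(1L, min(150L, d[1]), 1L, min(30L, d[2]), 1L, min(30L, d[3]))
}

check_box <- function(box, d) {
  box <- as.integer(box)
  if (length(box) != 6L) stop("bg_box must be (z1, z2, y1, y2, x1, x2)")
  if (any(box[c(1, 3, 5)] < 1L) || box[2] > d[1] || box[4] > d[2] ||
      box[6] > d[3] || any(box[c(2, 4, 6)] < box[c(1, 3, 5)])) {
    stop(sprintf("bg_box (%s) lies outside the %dx%dx%d volume",
                 paste(box, collapse = ", "), d[1], d[2], d[3]))
  }
  box
}

#' Temporal background reduction
#'
#' For every frame, the mean intensity inside a fixed box outside the
#' specimen is subtracted from the whole frame and a constant offset is
#' added back; negative values are floored at zero. Pins the box-region mean
#' at the offset, removing slow temporal drifts of the background level.
#'
#' @param vol a [volume_series()].
#' @param bg_box voxel box `(z1, z2, y1, y2, x1, x2)`, by contract outside
#'   the specimen; defaults to [default_background_box()].
#' @param offset counts added after subtraction (default 1000).
#' @return the corrected [volume_series()].
#' @export
subtract_temporal_background <- function(vol, bg_box = default_background_box(vol),
                                         offset = 1000) {
  stopifnot(inherits(vol, "volume_series"))
  d <- dim(vol$frames[[1]])
  box <- check_box(bg_box, d)
  vol$frames <- lapply(vol$frames, function(f) {
    m <- mean(f[box[1]:box[2], box[3]:box[4], box[5]:box[6]])
    f <- f - m + offset
    f[f < 0] <- 0
    f
  })
  vol
}

#' Pairwise integer translation by cross-correlation
#'
#' Default pairwise estimator for [register_recursive()]: the integer-voxel
#' translation maximizing the circular cross-correlation between the two
#' frames (FFT-based).
#'
#' @param ref,mov 3D arrays of the same shape.
#' @return integer translation `(z, y, x)` in voxels that, applied to `mov`,
#'   best aligns it with `ref`.
#' @export
estimate_translation_xcorr <- function(ref, mov) {
  d <- dim(ref)
  cc <- Re(stats::fft(stats::fft(ref) * Conj(stats::fft(mov)), inverse = TRUE))
  k <- arrayInd(which.max(cc), d) - 1L
  shift <- ifelse(k > d / 2, k - d, k)
  as.integer(shift)
}

#' Recursive time-series registration
#'
#' Registers a volume series by recursive reference propagation: the
#' transform of frame `n + 1` is estimated against the already-transformed
#' frame `n` and applied, the result serving as the reference for the next
#' frame. If the reference is not the first frame, the procedure is also
#' propagated backwards from the reference. The pairwise estimator is
#' pluggable; the built-in default estimates integer-voxel translations by
#' cross-correlation.
#'
#' @param vol a [volume_series()].
#' @param pairwise_estimator function `(ref, mov) -> translation (z, y, x)`
#'   in voxels.
#' @param reference_index index of the reference frame.
#' @param fill intensity filled into voxels vacated by the translation
#'   (default 1000, the background offset).
#' @return list with `volume` (registered series) and `transforms` (list of
#'   per-frame voxel translations).
#' @export
register_recursive <- function(vol, pairwise_estimator = estimate_translation_xcorr,
                               reference_index = 1L, fill = 1000) {
  stopifnot(inherits(vol, "volume_series"))
  n_t <- length(vol$frames)
  if (reference_index < 1L || reference_index > n_t) {
    stop("reference_index must be between 1 and ", n_t)
  }
  frames <- vol$frames
  transforms <- rep(list(c(0L, 0L, 0L)), n_t)
  run <- function(idx_seq) {
    ref <- frames[[reference_index]]
    for (i in idx_seq) {
      sh <- tryCatch(pairwise_estimator(ref, frames[[i]]), error = function(e) {
        stop(sprintf("pairwise estimator failed on frame pair (%d, %d): %s",
                     i - sign(i - reference_index), i, conditionMessage(e)))
      })
      if (length(sh) != 3L || any(!is.finite(sh))) {
        stop(sprintf("pairwise estimator returned an invalid transform for frame pair (%d, %d)",
                     i - sign(i - reference_index), i))
      }
      frames[[i]] <<- shift_array(frames[[i]], sh, fill = fill)
      transforms[[i]] <<- as.integer(round(sh))
      ref <- frames[[i]]
    }
  }
  if (reference_index < n_t) run((reference_index + 1L):n_t)
  if (reference_index > 1L) run((reference_index - 1L):1L)
  vol$frames <- frames
  list(volume = vol, transforms = transforms)
}

#' Center-of-mass axis alignment
#'
#' Thresholds every frame into a binary mask, sums the masks over all
#' timepoints and computes the center of mass (COM) of the summed mask; the
#' whole 4D dataset is translated so the COM sits at the image center, then
#' rotated about the COM by the supplied (operator-determined) angles so the
#' anteroposterior and proximodistal axes match the y and z image axes.
#'
#' @param vol a [volume_series()].
#' @param threshold binary mask threshold in counts (default 1030).
#' @param rotation_angles rotation angles in degrees about the `(z, y, x)`
#'   axes, applied in that order.
#' @param fill fill value for vacated voxels (default 1000).
#' @return list with `volume` (aligned series) and `alignment`, a list with
#'   per-frame translation (um and voxels), rotation angles, COM (um and
#'   voxel coordinates) and the summed-mask voxel count.
#' @export
align_by_mask_com <- function(vol, threshold = 1030,
                              rotation_angles = c(0, 0, 0), fill = 1000) {
  stopifnot(inherits(vol, "volume_series"))
  d <- dim(vol$frames[[1]])
  summed <- array(0, dim = d)
  for (f in vol$frames) summed <- summed + (f > threshold)
  tot <- sum(summed)
  if (tot == 0) {
    stop("no voxel above threshold ", threshold, "; mask is empty")
  }
  com_vox <- c(
    sum(slice.index(summed, 1L) * summed),
    sum(slice.index(summed, 2L) * summed),
    sum(slice.index(summed, 3L) * summed)) / tot
  center_vox <- (d + 1) / 2
  shift_vox <- round(center_vox - com_vox)
  vol$frames <- lapply(vol$frames, shift_array, shift = shift_vox, fill = fill)
  if (any(rotation_angles != 0)) {
    vol$frames <- lapply(vol$frames, rotate_about, angles = rotation_angles,
                         center_vox = center_vox, fill = fill)
  }
  alignment <- list(
    translation_vox = as.integer(shift_vox),
    translation_um = shift_vox * vol$spacing,
    rotation_angles = rotation_angles,
    com_vox = com_vox,
    com_um = (com_vox - 1) * vol$spacing,
    mask_voxels = sum(summed > 0)
  )
  list(volume = vol, alignment = alignment)
}

# Rotate a 3D array about a voxel center by angles (deg) around z, y, x.
rotate_about <- function(a, angles, center_vox, fill = 0) {
  th <- angles * pi / 180
  rz <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  rx <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0),
              c(0, 0, 1))
  rot <- rx %*% ry %*% rz
  d <- dim(a)
  grid <- cbind(as.numeric(slice.index(a, 1L)), as.numeric(slice.index(a, 2L)),
                as.numeric(slice.index(a, 3L)))
  rel <- sweep(grid, 2L, center_vox)
  src <- rel %*% rot + matrix(center_vox, nrow(rel), 3L, byrow = TRUE)
  array(trilinear(a, src, fill = fill), dim = d)
}

#' Resample a volume to isotropic resolution
#'
#' Linear interpolation along z resizes the axial dimension by `z_factor`;
#' x and y are untouched. `"auto"` derives the factor from the spacing ratio
#' (e.g. 7.5 um z-steps over 2.088 um lateral pixels give 3.59).
#'
#' @param vol a [volume_series()].
#' @param z_factor resize factor for z, or `"auto"`.
#' @return the resampled [volume_series()] with isotropic spacing when the
#'   factor matches the spacing ratio.
#' @export
resample_isotropic <- function(vol, z_factor = "auto") {
  stopifnot(inherits(vol, "volume_series"))
  if (identical(z_factor, "auto")) z_factor <- vol$spacing[1] / vol$spacing[2]
  if (z_factor <= 0) stop("z_factor must be > 0")
  if (abs(z_factor - 1) < 1e-12) return(vol)
  d <- dim(vol$frames[[1]])
  nz_out <- floor((d[1] - 1) * z_factor) + 1L
  src <- (seq_len(nz_out) - 1) / z_factor
  i0 <- pmin(floor(src) + 1L, d[1] - 1L)
  w <- src - (i0 - 1)
  vol$frames <- lapply(vol$frames, function(f) {
    out <- array(0, dim = c(nz_out, d[2], d[3]))
    for (i in seq_len(nz_out)) {
      out[i, , ] <- (1 - w[i]) * f[i0[i], , ] + w[i] * f[i0[i] + 1L, , ]
    }
    out
  })
  vol$spacing[1] <- vol$spacing[1] / z_factor
  vol
}

#' Subsample a volume in x and y
#'
#' Integer factors use block-mean downsampling; rational factors (e.g. 3.75)
#' fall back to linear resampling at the subsampled grid positions. Spacing
#' is scaled accordingly.
#'
#' @param vol a [volume_series()].
#' @param factor subsampling factor >= 1.
#' @return the subsampled [volume_series()].
#' @export
subsample_xy <- function(vol, factor) {
  stopifnot(inherits(vol, "volume_series"))
  if (factor < 1) stop("factor must be >= 1")
  if (factor == 1) return(vol)
  d <- dim(vol$frames[[1]])
  if (factor == round(factor)) {
    f <- as.integer(factor)
    ny <- d[2] %/% f; nx <- d[3] %/% f
    if (ny < 2L || nx < 2L) stop("factor leaves fewer than 2 voxels in x or y")
    vol$frames <- lapply(vol$frames, function(a) {
      a <- a[, seq_len(ny * f), seq_len(nx * f), drop = FALSE]
      a <- array(a, dim = c(d[1], f, ny, f, nx))
      ap <- apply(a, c(1L, 3L, 5L), mean)
      ap
    })
  } else {
    ny <- floor((d[2] - 1) / factor) + 1L
    nx <- floor((d[3] - 1) / factor) + 1L
    if (ny < 2L || nx < 2L) stop("factor leaves fewer than 2 voxels in x or y")
    sy <- (seq_len(ny) - 1) * factor + 1
    sx <- (seq_len(nx) - 1) * factor + 1
    vol$frames <- lapply(vol$frames, function(a) {
      out <- array(0, dim = c(d[1], ny, nx))
      j0 <- pmin(floor(sy), d[2] - 1L); wj <- sy - j0
      k0 <- pmin(floor(sx), d[3] - 1L); wk <- sx - k0
      tmp <- array(0, dim = c(d[1], ny, d[3]))
      for (j in seq_len(ny)) {
        tmp[, j, ] <- (1 - wj[j]) * a[, j0[j], ] + wj[j] * a[, j0[j] + 1L, ]
      }
      for (k in seq_len(nx)) {
        out[, , k] <- (1 - wk[k]) * tmp[, , k0[k]] + wk[k] * tmp[, , k0[k] + 1L]
      }
      out
    })
  }
  vol$spacing[2:3] <- vol$spacing[2:3] * factor
  vol
}
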