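#' Surface path through three anchors with chorded arc-length table
#'
#' Builds the line of interest through the proximal origin, an intermediate
#' surface point and a distal end. The interpolant is the constant-curvature
#' conic (circular arc) through the three anchors, which degenerates to the
#' straight polyline when the anchors are collinear; it is exact on circular
#' meridians and close to any smooth surface arc at this anchor spacing.
#' The arc is chorded by dividing the curve parameter `u` in `[0, 1]` into
#' `n_segments` equal pieces; cumulative segment lengths are tabulated so
#' that integer-distance lookups along the arc are a table search.
#'
#' @param origin,intermediate,distal 3D points `(z, y, x)` in micrometers.
#' @param n_segments number of chord segments (default 100,000).
#' @return an object of class `surface_path` with fields `anchors`,
#'   `point_at` (vectorized map from `u` to 3D points), `cum` (cumulative
#'   chord length per `u` sample), `total_length` and `n_segments`.
#' @export
build_surface_path <- function(origin, intermediate, distal,
                               n_segments = 100000L) {
  p0 <- as.numeric(origin); p1 <- as.numeric(intermediate)
  p2 <- as.numeric(distal)
  stopifnot(length(p0) == 3L, length(p1) == 3L, length(p2) == 3L)
  if (n_segments < 1L) stop("n_segments must be >= 1")
  a <- p1 - p0; b <- p2 - p0
  la <- sqrt(sum(a^2)); lb <- sqrt(sum((p2 - p1)^2)); lc <- sqrt(sum(b^2))
  if (la == 0 || lb == 0 || lc == 0) {
    stop("anchors must be three distinct points")
  }
  cr <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  collinear <- sqrt(sum(cr^2)) <= 1e-9 * la * lc
  if (collinear) {
    # straight polyline, u proportional to chord length
    u1 <- la / (la + lb)
    point_at <- function(u) {
      u <- pmin(pmax(u, 0), 1)
      first <- u <= u1
      t1 <- if (u1 > 0) u / u1 else rep(0, length(u))
      t2 <- if (u1 < 1) (u - u1) / (1 - u1) else rep(1, length(u))
      out <- matrix(NA_real_, nrow = length(u), ncol = 3L)
      for (d in 1:3) {
        out[, d] <- ifelse(first, p0[d] + t1 * (p1[d] - p0[d]),
                           p1[d] + t2 * (p2[d] - p1[d]))
      }
      out
    }
    type <- "segment"
  } else {
    # circumcircle of the anchor triangle, in its own plane
    e1 <- b / lc
    n <- cr / sqrt(sum(cr^2))
    e2 <- c(n[2] * e1[3] - n[3] * e1[2],
            n[3] * e1[1] - n[1] * e1[3],
            n[1] * e1[2] - n[2] * e1[1])
    q1 <- c(sum(a * e1), sum(a * e2))     # p1 in plane coords (p0 at origin)
    q2 <- c(lc, 0)                        # p2 in plane coords
    # perpendicular bisectors: |c|^2 = |c-q1|^2 = |c-q2|^2
    m <- rbind(2 * q1, 2 * q2)
    rhs <- c(sum(q1^2), sum(q2^2))
    cen <- solve(m, rhs)
    r <- sqrt(sum(cen^2))
    th0 <- atan2(-cen[2], -cen[1])
    th1 <- atan2(q1[2] - cen[2], q1[1] - cen[1])
    th2 <- atan2(q2[2] - cen[2], q2[1] - cen[1])
    d1 <- (th1 - th0) %% (2 * pi)
    d2 <- (th2 - th0) %% (2 * pi)
    sweep <- if (d1 <= d2) d2 else d2 - 2 * pi  # pass through the intermediate
    point_at <- function(u) {
      u <- pmin(pmax(u, 0), 1)
      th <- th0 + u * sweep
      px <- cen[1] + r * cos(th)
      py <- cen[2] + r * sin(th)
      cbind(p0[1] + px * e1[1] + py * e2[1],
            p0[2] + px * e1[2] + py * e2[2],
            p0[3] + px * e1[3] + py * e2[3])
    }
    type <- "arc"
  }
  u <- seq(0, 1, length.out = n_segments + 1L)
  pts <- point_at(u)
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  rm(u, pts, seg)  # point_at's environment is this frame; keep it lean
  structure(
    list(anchors = rbind(origin = p0, intermediate = p1, distal = p2),
         point_at = point_at, cum = cum,
         total_length = cum[length(cum)],
         n_segments = as.integer(n_segments), type = type),
    class = "surface_path"
  )
}

#' @export
print.surface_path <- function(x, ...) {
  cat(sprintf("<surface_path> %s through 3 anchors, length %.2f um (%d chord segments)\n",
              x$type, x$total_length, x$n_segments))
  invisible(x)
}

#' Look up points along a surface path by arc distance
#'
#' Returns, for each requested cumulative arc distance, the `u` value whose
#' tabulated cumulative chord length is closest, together with the curve
#' point there.
#'
#' @param path a [build_surface_path()] object.
#' @param distances cumulative arc distances in micrometers; values beyond
#'   the total length return `NA`.
#' @return list with `u`, `points` (n x 3 matrix `(z, y, x)`) and
#'   `cum_length` (the tabulated length actually attained).
#' @export
arc_lookup <- function(path, distances) {
  stopifnot(inherits(path, "surface_path"))
  cum <- path$cum
  n <- length(cum)
  u <- rep(NA_real_, length(distances))
  ok <- distances >= 0 & distances <= path$total_length
  if (any(ok)) {
    i <- findInterval(distances[ok], cum, all.inside = TRUE)
    lo <- cum[i]; hi <- cum[i + 1L]
    pick <- ifelse(distances[ok] - lo <= hi - distances[ok], i, i + 1L)
    u[ok] <- (pick - 1) / (n - 1)
  }
  pts <- matrix(NA_real_, nrow = length(distances), ncol = 3L)
  if (any(ok)) pts[ok, ] <- path$point_at(u[ok])
  list(u = u, points = pts,
       cum_length = ifelse(ok, cum[pmax(1L, round(u * (n - 1)) + 1L)], NA_real_))
}
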