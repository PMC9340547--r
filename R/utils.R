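# Internal numeric helpers shared across modules.

# Run `code` under a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Reflect-pad a vector by `k` samples on each side (no repeated edge sample).
reflect_pad <- function(x, k) {
  n <- length(x)
  if (k <= 0L) return(x)
  if (n < 2L) stop("cannot reflect-pad a series of length < 2")
  k <- as.integer(k)
  if (k > n - 1L) stop("series too short to reflect-pad by ", k, " samples")
  # mirror: x[k+1], ..., x[2] | x | x[n-1], ..., x[n-k]
  left <- x[pmin(n, (k + 1L):2L)]
  right <- x[pmax(1L, (n - 1L):(n - k))]
  c(left, x, right)
}

gaussian_kernel <- function(sigma, truncate = 4) {
  if (sigma <= 0) return(1)
  half <- max(1L, as.integer(ceiling(truncate * sigma)))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k / sum(k)
}

# 1D convolution with reflect-padded boundaries; kernel must be odd-length.
convolve_reflect <- function(x, kernel) {
  nk <- length(kernel)
  if (nk == 1L) return(x * kernel)
  half <- (nk - 1L) %/% 2L
  xp <- reflect_pad(x, half)
  out <- stats::filter(xp, kernel, method = "convolution", sides = 2L)
  as.numeric(out[(half + 1L):(half + length(x))])
}

# Apply a 1D kernel along one margin of a 3D array (reflect boundaries).
# Uses stats::filter on a (dim, rest) matrix, which runs at C speed.
filter_along <- function(a, kernel, margin) {
  d <- dim(a)
  nk <- length(kernel)
  if (nk == 1L) return(a * kernel)
  half <- (nk - 1L) %/% 2L
  perm <- c(margin, setdiff(seq_along(d), margin))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[margin])
  n <- nrow(m)
  if (n < 2L) stop("axis too short for smoothing kernel")
  top <- m[pmin(n, (half + 1L):2L), , drop = FALSE]
  bot <- m[pmax(1L, (n - 1L):(n - half)), , drop = FALSE]
  mp <- rbind(top, m, bot)
  f <- stats::filter(mp, kernel, method = "convolution", sides = 2L)
  f <- matrix(as.numeric(f), nrow = nrow(mp))[(half + 1L):(half + n), , drop = FALSE]
  ap <- array(f, dim = d[perm])
  aperm(ap, order(perm))
}

# Separable 3D Gaussian smoothing (sigma in voxels, scalar or per-axis).
gaussian_smooth3 <- function(a, sigma) {
  sigma <- rep_len(sigma, 3L)
  for (ax in 1:3) {
    if (sigma[ax] > 0) a <- filter_along(a, gaussian_kernel(sigma[ax]), ax)
  }
  a
}

# Trilinear interpolation of a 3D array at fractional voxel indices
# (1-based, matrix of n x 3 in array order). Out-of-bounds -> `fill`.
trilinear <- function(a, idx, fill = 0) {
  d <- dim(a)
  i <- idx[, 1]; j <- idx[, 2]; k <- idx[, 3]
  ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  out <- rep(fill, nrow(idx))
  if (!any(ok)) return(out)
  i <- i[ok]; j <- j[ok]; k <- k[ok]
  i0 <- pmin(pmax(floor(i), 1), d[1] - 1L); fi <- i - i0
  j0 <- pmin(pmax(floor(j), 1), d[2] - 1L); fj <- j - j0
  k0 <- pmin(pmax(floor(k), 1), d[3] - 1L); fk <- k - k0
  if (d[1] == 1L) { i0 <- rep(1, length(i)); fi <- 0 }
  if (d[2] == 1L) { j0 <- rep(1, length(j)); fj <- 0 }
  if (d[3] == 1L) { k0 <- rep(1, length(k)); fk <- 0 }
  at <- function(ii, jj, kk) a[cbind(ii, jj, kk)]
  v <- at(i0, j0, k0) * (1 - fi) * (1 - fj) * (1 - fk) +
    at(i0 + 1, j0, k0) * fi * (1 - fj) * (1 - fk) +
    at(i0, j0 + 1, k0) * (1 - fi) * fj * (1 - fk) +
    at(i0, j0, k0 + 1) * (1 - fi) * (1 - fj) * fk +
    at(i0 + 1, j0 + 1, k0) * fi * fj * (1 - fk) +
    at(i0 + 1, j0, k0 + 1) * fi * (1 - fj) * fk +
    at(i0, j0 + 1, k0 + 1) * (1 - fi) * fj * fk +
    at(i0 + 1, j0 + 1, k0 + 1) * fi * fj * fk
  out[ok] <- v
  out
}

#' Unwrap a sequence of phases
#'
#' Removes 2*pi jumps from a sequence of wrapped phase values so that
#' successive differences lie in (-pi, pi].
#'
#' @param phi numeric vector of phases in radians.
#' @return numeric vector of unwrapped phases; `phi[1]` is kept as is.
#' @export
unwrap_phase <- function(phi) {
  if (length(phi) < 2L) return(phi)
  dp <- diff(phi)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  cumsum(c(phi[1], dp))
}

# Wrap radians to (-pi, pi].
wrap_phase <- function(phi) {
  w <- phi - 2 * pi * floor((phi + pi) / (2 * pi))
  w[w <= -pi] <- pi
  w
}

# Integer-shift a 3D array by `shift` voxels (array-order), fill vacated.
shift_array <- function(a, shift, fill = 0) {
  d <- dim(a)
  shift <- as.integer(round(shift))
  if (all(shift == 0L)) return(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    s <- shift[ax]
    if (abs(s) >= d[ax]) return(out)
    if (s >= 0) {
      src[[ax]] <- 1L:(d[ax] - s); dst[[ax]] <- (1L + s):d[ax]
    } else {
      src[[ax]] <- (1L - s):d[ax]; dst[[ax]] <- 1L:(d[ax] + s)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
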