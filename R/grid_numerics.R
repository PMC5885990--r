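# Shared finite-difference / smoothing / interpolation kernel used by every
# evolution routine. All math runs on plain 3-D arrays with unit grid step;
# the clamp-to-edge rule handles boundaries everywhere (stencils, convolution
# and interpolation alike), so a replicated edge value yields a zero one-sided
# difference at the clamped face.

AXES <- c(x = 1L, y = 2L, z = 3L)

# Gather neighbour values along `axis`, offset `by` nodes, clamped at faces.
shift_clamp <- function(a, axis, by) {
  d <- dim(a)
  n <- d[axis]
  idx <- pmin.int(pmax.int(seq_len(n) + as.integer(by), 1L), n)
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

#' One-sided finite difference of a scalar field
#'
#' Forward difference `D+ phi = phi(i+1) - phi(i)` or backward difference
#' `D- phi = phi(i) - phi(i-1)` along one axis, with unit grid step.
#' Edge values are replicated, so the one-sided difference at the clamped
#' face is zero.
#'
#' @param field 3-D numeric array (or matrix / [image_volume()]).
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param direction `"forward"` or `"backward"`.
#' @return array of the same shape.
#' @export
finite_difference <- function(field, axis = c("x", "y", "z"),
                              direction = c("forward", "backward")) {
  axis <- match.arg(axis)
  direction <- match.arg(direction)
  a <- as_field3d(field)
  ax <- AXES[[axis]]
  if (dim(a)[ax] < 2L) return(array(0, dim(a)))
  if (direction == "forward") shift_clamp(a, ax, 1L) - a else a - shift_clamp(a, ax, -1L)
}

#' Minmod limiter
#'
#' `m(x, y) = sign(x) * min(|x|, |y|)` when `x * y >= 0`, and 0 otherwise.
#' Vectorized over its arguments.
#'
#' @param x,y numeric vectors or arrays of equal shape.
#' @return numeric of the same shape as `x`.
#' @export
minmod <- function(x, y) {
  out <- sign(x) * pmin(abs(x), abs(y))
  out[x * y < 0] <- 0
  out
}

#' Minmod upwind gradient and regularized norm
#'
#' Per-axis gradient component `m(D+ phi, D- phi)` (minmod of the forward and
#' backward differences) and the alpha-regularized norm
#' `sqrt(alpha^2 + sum of squared components)`, which is bounded below by
#' `alpha` so that force fields dividing by it stay finite.
#'
#' @param phi 3-D scalar field.
#' @param alpha small positive norm regularizer (default `1e-4`).
#' @return list with `grad` (4-D array, last dimension = axis) and `norm`
#'   (3-D array, `>= alpha` everywhere).
#' @export
minmod_gradient <- function(phi, alpha = 1e-4) {
  stopifnot(alpha > 0)
  a <- as_field3d(phi)
  d <- dim(a)
  grad <- array(0, c(d, 3L))
  nsq <- array(alpha^2, d)
  for (ax in 1:3) {
    if (d[ax] < 2L) next
    g <- minmod(shift_clamp(a, ax, 1L) - a, a - shift_clamp(a, ax, -1L))
    grad[, , , ax] <- g
    nsq <- nsq + g * g
  }
  list(grad = grad, norm = sqrt(nsq))
}

# Sampled 1-D Gaussian kernel, truncated at `truncate * sigma`, renormalized.
gaussian_kernel <- function(sigma, truncate = 4) {
  r <- max(1L, ceiling(truncate * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

conv_axis_clamped <- function(a, kernel, axis) {
  r <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim(a))
  for (o in seq(-r, r)) {
    out <- out + kernel[o + r + 1L] * shift_clamp(a, axis, o)
  }
  out
}

#' Separable Gaussian smoothing
#'
#' Discrete convolution with a sampled Gaussian kernel, truncated at
#' `truncate * sigma` and renormalized to sum one; boundaries are handled by
#' edge replication. `sigma = 0` (per axis) is the identity. 4-D vector
#' fields are smoothed componentwise.
#'
#' @param field 3-D scalar field or 4-D vector field (last dim = components).
#' @param sigma standard deviation in voxels, scalar or one value per axis.
#' @param truncate kernel support radius in units of sigma (default 4).
#' @return the smoothed field, same shape and type as the input.
#' @export
gaussian_smooth <- function(field, sigma, truncate = 4) {
  sigma <- rep_len(as.numeric(sigma), 3L)
  if (any(sigma < 0)) stop("`sigma` must be non-negative", call. = FALSE)
  if (is.array(field) && length(dim(field)) == 4L) {
    out <- field
    for (cc in seq_len(dim(field)[4])) {
      out[, , , cc] <- gaussian_smooth(field[, , , cc], sigma, truncate)
    }
    return(out)
  }
  a <- as_field3d(field)
  if (all(sigma == 0)) return(a)
  for (ax in 1:3) {
    if (sigma[ax] == 0 || dim(a)[ax] < 2L) next
    a <- conv_axis_clamped(a, gaussian_kernel(sigma[ax], truncate), ax)
  }
  a
}

#' Trilinear interpolation at continuous grid coordinates
#'
#' Samples a scalar field at arbitrary continuous positions (0-based,
#' node-centered voxel coordinates). Coordinates outside the grid are clamped
#' to the domain boundary before interpolation; the result at a grid node is
#' that node's value exactly, and interpolation is exact on affine fields.
#'
#' @param field 3-D scalar field.
#' @param points numeric matrix with one row per query point, columns (x, y, z).
#' @return numeric vector of interpolated values, one per row of `points`.
#' @export
interpolate <- function(field, points) {
  a <- as_field3d(field)
  d <- dim(a)
  p <- as_points(points)
  n <- nrow(p)
  i0 <- f <- vector("list", 3L)
  for (ax in 1:3) {
    x <- pmin(pmax(p[, ax], 0), d[ax] - 1L)
    if (d[ax] == 1L) {
      i0[[ax]] <- rep.int(0L, n)
      f[[ax]] <- rep.int(0, n)
    } else {
      lo <- pmin.int(floor(x), d[ax] - 2L)
      i0[[ax]] <- as.integer(lo)
      f[[ax]] <- x - lo
    }
  }
  # linear index of corner (dx, dy, dz) relative to (i0, j0, k0); 1-based
  base <- 1L + i0[[1L]] + d[1L] * (i0[[2L]] + d[2L] * i0[[3L]])
  sx <- 1L; sy <- d[1L]; sz <- d[1L] * d[2L]
  fx <- f[[1L]]; fy <- f[[2L]]; fz <- f[[3L]]
  gx <- 1 - fx; gy <- 1 - fy; gz <- 1 - fz
  ex <- as.integer(d[1L] > 1L) * sx
  ey <- as.integer(d[2L] > 1L) * sy
  ez <- as.integer(d[3L] > 1L) * sz
  v <- a[base]                 * gx * gy * gz +
       a[base + ex]            * fx * gy * gz +
       a[base + ey]            * gx * fy * gz +
       a[base + ex + ey]       * fx * fy * gz +
       a[base + ez]            * gx * gy * fz +
       a[base + ex + ez]       * fx * gy * fz +
       a[base + ey + ez]       * gx * fy * fz +
       a[base + ex + ey + ez]  * fx * fy * fz
  as.numeric(v)
}

# 0-based voxel-center coordinates of every grid node, as an n x 3 matrix in
# array (column-major) order.
grid_coordinates <- function(d) {
  cbind(x = rep.int(seq_len(d[1L]) - 1, d[2L] * d[3L]),
        y = rep.int(rep(seq_len(d[2L]) - 1, each = d[1L]), d[3L]),
        z = rep(seq_len(d[3L]) - 1, each = d[1L] * d[2L]))
}

# Sample `field` at x + u(x) for every grid node x: the warped image
# I(U(x)) with clamped trilinear interpolation.
warp_scalar <- function(field, u) {
  a <- as_field3d(field)
  d <- dim(a)
  pts <- grid_coordinates(d)
  pts[, 1L] <- pts[, 1L] + as.vector(u[, , , 1L])
  pts[, 2L] <- pts[, 2L] + as.vector(u[, , , 2L])
  pts[, 3L] <- pts[, 3L] + as.vector(u[, , , 3L])
  array(interpolate(a, pts), d)
}

#' Linear min-max intensity normalization
#'
#' Rescales intensities linearly to the interval \[0, 1\]. A constant image
#' maps to all zeros (degenerate-range rule).
#'
#' @param image [image_volume()], matrix or 3-D array.
#' @return same type as the input, with values in \[0, 1\].
#' @export
normalize_intensities <- function(image) {
  a <- as_field3d(image)
  rng <- range(a)
  out <- if (rng[2] > rng[1]) (a - rng[1]) / (rng[2] - rng[1]) else array(0, dim(a))
  if (inherits(image, "image_volume")) image_volume(out, image$spacing) else out
}

#' Histogram matching by quantile mapping
#'
#' Monotone intensity remapping of the source so that its empirical CDF
#' matches the target's (type-1 quantile lookup). Voxel value ordering of the
#' source is preserved (ties allowed).
#'
#' @param source,target [image_volume()]s or arrays, typically normalized to
#'   \[0, 1\].
#' @return the remapped source, same type as `source`.
#' @export
histogram_match <- function(source, target) {
  s <- as_field3d(source)
  t_sorted <- sort(as.vector(as_field3d(target)))
  nt <- length(t_sorted)
  r <- rank(as.vector(s), ties.method = "max")
  # ceil(r * nt / n) in exact double arithmetic (r * nt <= 2^53)
  idx <- floor((r * nt - 1) / length(s)) + 1
  out <- array(t_sorted[pmax(1, idx)], dim(s))
  if (inherits(source, "image_volume")) image_volume(out, source$spacing) else out
}
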