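# Exact Euclidean distance transforms (separable lower-envelope algorithm)
# and small binary morphology helpers. Used for signed-distance level-set
# initialization, narrow-band construction and label-map hole closing.

BIG_DIST2 <- 1e12

# 1-D squared-distance transform of a sampled function f (lower envelope of
# parabolas); f = 0 at sites, BIG_DIST2 elsewhere.
edt1d_sq <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  for (q in 2:n) {
    repeat {
      vk <- v[k]
      s <- ((f[q] + q * q) - (f[vk] + vk * vk)) / (2 * q - 2 * vk)
      if (s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  d <- numeric(n)
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

apply_lines <- function(a, axis, fun) {
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  b <- aperm(a, perm)
  d <- dim(b)
  m <- matrix(b, nrow = d[1L])
  m <- apply(m, 2L, fun)
  b <- array(m, d)
  aperm(b, order(perm))
}

# Squared Euclidean distance from every voxel to the nearest TRUE voxel of
# `sites` (isotropic unit grid step).
edt_squared <- function(sites) {
  a <- array(ifelse(as.vector(sites), 0, BIG_DIST2), dim(sites))
  for (ax in 1:3) {
    if (dim(a)[ax] < 2L) next
    a <- apply_lines(a, ax, edt1d_sq)
  }
  a
}

#' Signed-distance level-set function of a binary mask
#'
#' Exact Euclidean (voxel-unit) signed distance: positive inside the mask,
#' negative outside, measured to the nearest voxel of the opposite class.
#' Used to initialize Chan--Vese evolution from a mask.
#'
#' @param mask logical/0-1 array, matrix or [label_map()] (nonzero = inside).
#' @return 3-D numeric array, positive inside.
#' @export
mask_to_levelset <- function(mask) {
  m <- as_field3d(mask) != 0
  if (!any(m)) return(array(-1, dim(m)))
  if (all(m)) return(array(1, dim(m)))
  sqrt(edt_squared(!m)) * m - sqrt(edt_squared(m)) * !m
}

# Offsets of the Euclidean ball of radius r (integer offsets, |o| <= r).
ball_offsets <- function(r) {
  ri <- floor(r)
  g <- expand.grid(ox = -ri:ri, oy = -ri:ri, oz = -ri:ri)
  g[g$ox^2 + g$oy^2 + g$oz^2 <= r^2, , drop = FALSE]
}

shift_pad_false <- function(m, o) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    n <- d[ax]; k <- o[[ax]]
    if (abs(k) >= n) return(out)
    if (k >= 0) { dst[[ax]] <- seq_len(n - k) + k; src[[ax]] <- seq_len(n - k) }
    else { dst[[ax]] <- seq_len(n + k); src[[ax]] <- seq_len(n + k) - k }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

binary_dilate <- function(m, r = 1) {
  off <- ball_offsets(r)
  out <- array(FALSE, dim(m))
  for (i in seq_len(nrow(off))) {
    out <- out | shift_pad_false(m, c(off$ox[i], off$oy[i], off$oz[i]))
  }
  out
}

binary_erode <- function(m, r = 1) !binary_dilate(!m, r)

binary_close <- function(m, r = 1) binary_erode(binary_dilate(m, r), r)

# Voxels of `mask` adjacent (6-neighbourhood) to the opposite class, on either
# side of the interface: the discrete region boundary.
boundary_voxels <- function(mask) {
  m <- mask != 0
  d <- dim(m)
  differs <- array(FALSE, d)
  for (ax in 1:3) {
    if (d[ax] < 2L) next
    for (o in c(-1L, 1L)) {
      nb <- array(shift_clamp(array(as.numeric(m), d), ax, o) != 0, d)
      differs <- differs | (nb != m)
    }
  }
  differs
}
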