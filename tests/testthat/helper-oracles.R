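# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately re-derive every quantity with plain nested loops and
# closed forms, sharing no code path with the package internals they check.

# One-sided differences, nodewise loops, clamped edges (zero difference).
oracle_finite_difference <- function(a, axis, direction) {
  d <- dim(a)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    idx <- c(i, j, k)
    nb <- idx
    nb[axis] <- idx[axis] + if (direction == "forward") 1L else -1L
    if (nb[axis] < 1L || nb[axis] > d[axis]) {
      out[i, j, k] <- 0
    } else if (direction == "forward") {
      out[i, j, k] <- a[nb[1], nb[2], nb[3]] - a[i, j, k]
    } else {
      out[i, j, k] <- a[i, j, k] - a[nb[1], nb[2], nb[3]]
    }
  }
  out
}

oracle_minmod <- function(x, y) {
  if (x * y < 0) return(0)
  sign(x) * min(abs(x), abs(y))
}

# Minmod gradient + alpha-regularized norm, scalar loops.
oracle_minmod_gradient <- function(a, alpha) {
  d <- dim(a)
  grad <- array(0, c(d, 3L))
  nrm <- array(0, d)
  fwd <- lapply(1:3, function(ax) oracle_finite_difference(a, ax, "forward"))
  bwd <- lapply(1:3, function(ax) oracle_finite_difference(a, ax, "backward"))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    s2 <- alpha^2
    for (ax in 1:3) {
      m <- oracle_minmod(fwd[[ax]][i, j, k], bwd[[ax]][i, j, k])
      grad[i, j, k, ax] <- m
      s2 <- s2 + m^2
    }
    nrm[i, j, k] <- sqrt(s2)
  }
  list(grad = grad, norm = nrm)
}

# Trilinear interpolation at one clamped point, scalar arithmetic.
oracle_interp1 <- function(a, p) {
  d <- dim(a)
  w <- numeric(3); i0 <- integer(3)
  for (ax in 1:3) {
    x <- min(max(p[ax], 0), d[ax] - 1)
    if (d[ax] == 1L) { i0[ax] <- 1L; w[ax] <- 0 }
    else {
      lo <- min(floor(x), d[ax] - 2)
      i0[ax] <- lo + 1L
      w[ax] <- x - lo
    }
  }
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- pmin(i0 + c(dx, dy, dz), d)
    wt <- (if (dx) w[1] else 1 - w[1]) * (if (dy) w[2] else 1 - w[2]) *
      (if (dz) w[3] else 1 - w[3])
    v <- v + wt * a[ii[1], ii[2], ii[3]]
  }
  v
}

# Vemuri force, nodewise: residual times minmod gradient of the warped
# source over its alpha-norm.
oracle_vemuri <- function(I_T, I_S, u, alpha) {
  d <- dim(I_T)
  warped <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- c(i, j, k) - 1 + u[i, j, k, ]
    warped[i, j, k] <- oracle_interp1(I_S, p)
  }
  g <- oracle_minmod_gradient(warped, alpha)
  out <- array(0, c(d, 3L))
  for (ax in 1:3) {
    out[, , , ax] <- (I_T - warped) * g$grad[, , , ax] / g$norm
  }
  out
}

# GCV1 force, nodewise, from a *given* stationary atlas gradient field
# (the smoothed-atlas construction itself is checked elsewhere).
oracle_gcv1 <- function(I_S, u, atlas_grad, s_values, c_in, c_out, alpha) {
  d <- dim(I_S)
  out <- array(0, c(d, 3L))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    s <- s_values[i, j, k]
    if (s == 0) next
    p <- c(i, j, k) - 1 + u[i, j, k, ]
    w <- oracle_interp1(I_S, p)
    g <- numeric(3)
    for (ax in 1:3) g[ax] <- oracle_interp1(atlas_grad[, , , ax], p)
    nrm <- sqrt(alpha^2 + sum(g^2))
    out[i, j, k, ] <- -s * ((w - c_in)^2 - (w - c_out)^2) * g / nrm
  }
  out
}

# Exhaustive squared distance from every voxel to the nearest TRUE voxel.
oracle_distance2 <- function(sites) {
  d <- dim(sites)
  pts <- which(sites, arr.ind = TRUE)
  out <- array(Inf, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    out[i, j, k] <- min((pts[, 1] - i)^2 + (pts[, 2] - j)^2 + (pts[, 3] - k)^2)
  }
  out
}

# Block means over factor^3 blocks, nested loops.
oracle_block_mean <- function(a, f) {
  d <- dim(a)
  dc <- ceiling(d / f)
  out <- array(0, dc)
  for (i in seq_len(dc[1])) for (j in seq_len(dc[2])) for (k in seq_len(dc[3])) {
    xi <- ((i - 1) * f + 1):min(i * f, d[1])
    yj <- ((j - 1) * f + 1):min(j * f, d[2])
    zk <- ((k - 1) * f + 1):min(k * f, d[3])
    out[i, j, k] <- mean(a[xi, yj, zk])
  }
  out
}

rand_field <- function(d, seed) {
  set.seed(seed)
  array(rnorm(prod(d)), d)
}

# Small two-lung toy label map: two well-separated boxes in a 16^3-ish grid.
toy_two_region_labels <- function(d = c(20L, 12L, 10L)) {
  lab <- array(0L, d)
  lab[3:6, 4:8, 3:7] <- 1L
  lab[14:17, 4:8, 3:7] <- 2L
  lab
}

# Fresh temporary directory per call, cleaned up by R's tempdir lifecycle.
withr_like_tempdir <- function() {
  d <- tempfile("lsreg-test-")
  dir.create(d)
  d
}
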