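test_that("finite differences match the definition and handle edges by clamping", {
  const <- array(3.7, c(4, 4, 3))
  for (dir in c("forward", "backward")) {
    expect_equal(finite_difference(const, "x", dir), array(0, dim(const)))
  }
  ramp <- array(rep(0:5, 4 * 3), c(6, 4, 3))  # phi_i = i along x
  fd <- finite_difference(ramp, "x", "forward")
  expect_equal(fd[1:5, , ], array(1, c(5, 4, 3)))
  expect_equal(fd[6, , ], matrix(0, 4, 3))    # clamped face: zero difference
  a <- rand_field(c(5, 4, 3), seed = 11)
  for (ax in 1:3) for (dir in c("forward", "backward")) {
    expect_equal(finite_difference(a, c("x", "y", "z")[ax], dir),
                 oracle_finite_difference(a, ax, dir))
  }
  expect_error(finite_difference(a, "w"), "arg")
})

test_that("minmod selects the smaller-magnitude agreeing difference", {
  expect_identical(minmod(2, 3), 2)
  expect_identical(minmod(-1, -4), -1)
  expect_identical(minmod(2, -3), 0)
  expect_identical(minmod(0, 5), 0)
  # vectorized over arrays
  x <- c(2, -1, 2, 0.5)
  y <- c(3, -4, -3, 0.2)
  expect_equal(minmod(x, y), c(2, -1, 0, 0.2))
})

test_that("minmod gradient and regularized norm match the nodewise oracle", {
  alpha <- 1e-4
  const <- array(2, c(5, 5, 4))
  g <- minmod_gradient(const, alpha)
  expect_equal(g$grad, array(0, c(5, 5, 4, 3)))
  expect_equal(g$norm, array(alpha, c(5, 5, 4)))
  ramp <- array(rep(0:5, 25), c(6, 5, 5))
  g <- minmod_gradient(ramp, alpha)
  expect_equal(g$grad[3, 3, 3, ], c(1, 0, 0))
  expect_equal(g$norm[3, 3, 3], sqrt(1 + alpha^2))
  a <- rand_field(c(6, 6, 6), seed = 21)
  got <- minmod_gradient(a, alpha)
  want <- oracle_minmod_gradient(a, alpha)
  expect_equal(got$grad, want$grad)
  expect_equal(got$norm, want$norm)
  expect_true(all(got$norm >= alpha))
})

test_that("gaussian smoothing is normalized, linear, and exact for sigma 0", {
  const <- array(1.5, c(8, 8, 4))
  expect_equal(gaussian_smooth(const, 2), const)
  a <- rand_field(c(8, 8, 4), seed = 31)
  expect_identical(gaussian_smooth(a, 0), a)
  # 1-D impulse against a dense convolution with the same truncated kernel
  imp <- array(0, c(21, 1, 1))
  imp[11, 1, 1] <- 1
  got <- gaussian_smooth(imp, 1)
  r <- ceiling(4 * 1)
  k <- dnorm(-r:r, sd = 1); k <- k / sum(k)
  expect_equal(as.vector(got)[(11 - r):(11 + r)], rev(k), tolerance = 1e-12)
  # linearity
  b <- rand_field(c(8, 8, 4), seed = 32)
  expect_equal(gaussian_smooth(2 * a + 3 * b, 1.5),
               2 * gaussian_smooth(a, 1.5) + 3 * gaussian_smooth(b, 1.5),
               tolerance = 1e-10)
  expect_error(gaussian_smooth(a, -1), "non-negative")
})

test_that("trilinear interpolation reproduces nodes, affine fields, and local bounds", {
  a <- rand_field(c(6, 5, 4), seed = 41)
  nodes <- cbind(c(0, 5, 2), c(0, 4, 3), c(0, 3, 1))
  expect_equal(interpolate(a, nodes),
               c(a[1, 1, 1], a[6, 5, 4], a[3, 4, 2]))
  mid <- array(0, c(2, 1, 1)); mid[2, 1, 1] <- 1
  expect_equal(interpolate(mid, cbind(0.5, 0, 0)), 0.5)
  # exact on affine fields at random interior points
  d <- c(7, 6, 5)
  co <- expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1), z = 0:(d[3] - 1))
  f <- array(1.5 + 0.3 * co$x - 0.7 * co$y + 0.2 * co$z, d)
  set.seed(42)
  q <- cbind(runif(20, 0, d[1] - 1), runif(20, 0, d[2] - 1), runif(20, 0, d[3] - 1))
  expect_equal(interpolate(f, q), 1.5 + 0.3 * q[, 1] - 0.7 * q[, 2] + 0.2 * q[, 3],
               tolerance = 1e-12)
  # bounded by the min/max of the 8 surrounding nodes; clamped outside
  v <- interpolate(a, q)
  expect_true(all(v >= min(a) - 1e-12 & v <= max(a) + 1e-12))
  expect_equal(interpolate(a, cbind(-5, -5, -5)), a[1, 1, 1])
  expect_equal(interpolate(a, cbind(100, 100, 100)), a[6, 5, 4])
})

test_that("intensity normalization is a linear map to [0,1] with a degenerate-range rule", {
  set.seed(12)
  a <- array(runif(24, 10, 20), c(4, 3, 2))
  a[1:3] <- c(10, 20, 15)
  n <- normalize_intensities(a)
  expect_equal(range(n), c(0, 1))
  expect_equal(n[3], 0.5)
  expect_equal(normalize_intensities(array(7, c(3, 3, 3))), array(0, c(3, 3, 3)))
  b <- array(c(0, runif(22), 1), c(4, 3, 2))
  expect_equal(normalize_intensities(b), b)
})

test_that("histogram matching is a monotone quantile map", {
  set.seed(5)
  src <- array(runif(60), c(5, 4, 3))
  expect_equal(histogram_match(src, src), src)
  # two-level source onto two-level target with matching proportions
  s2 <- array(rep(c(0.2, 0.8), 30), c(5, 4, 3))
  t2 <- array(rep(c(0.3, 0.9), 30), c(5, 4, 3))
  m <- histogram_match(s2, t2)
  expect_equal(sort(unique(as.vector(m))), c(0.3, 0.9))
  expect_equal(m == 0.9, s2 == 0.8)
  # rank preservation on arbitrary inputs
  tgt <- array(rnorm(60), c(5, 4, 3))
  out <- histogram_match(src, tgt)
  expect_true(all(diff(as.vector(out)[order(as.vector(src))]) >= 0))
})
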