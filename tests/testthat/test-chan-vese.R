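test_that("region means average each side of the contour with the zero level inside", {
  img <- array(c(0.1, 0.2, 0.9, 0.8), c(2, 2, 1))  # columns: (0.1,0.2), (0.9,0.8)
  phi <- array(c(-1, -1, 1, 1), c(2, 2, 1))        # right column inside
  m <- region_means(img, phi)
  expect_equal(m$c1, 0.85)
  expect_equal(m$c2, 0.15)
  expect_false(m$collapsed)
  ind <- array(rep(c(0, 1), 8), c(4, 2, 2))
  mi <- region_means(ind, ind - 0.5)  # phi > 0 exactly on the 1s
  expect_equal(c(mi$c1, mi$c2), c(1, 0))
  u <- array(0.42, c(3, 3, 3))
  mu_ <- region_means(u, rand_field(c(3, 3, 3), 7))
  expect_equal(c(mu_$c1, mu_$c2), c(0.42, 0.42))
  flagged <- region_means(u, array(1, c(3, 3, 3)))
  expect_true(flagged$collapsed)
  expect_equal(flagged$c2, 0)
})

test_that("the energy matches a direct voxelwise summation", {
  # perfectly matched piecewise-constant partition, mu = 0
  img <- array(0.2, c(6, 6, 3)); img[4:6, , ] <- 0.7
  phi <- array(-1, c(6, 6, 3)); phi[4:6, , ] <- 1
  expect_equal(chan_vese_energy(img, phi, mu = 0), 0)
  # uniform image: region terms vanish for any phi
  expect_equal(chan_vese_energy(array(0.3, c(5, 5, 2)),
                                rand_field(c(5, 5, 2), 3), mu = 0), 0)
  # toy image against an independent dense sum of the functional
  set.seed(9)
  a <- array(runif(27), c(3, 3, 3))
  p <- array(rnorm(27), c(3, 3, 3))
  mu <- 0.37; eps <- 1
  inside <- p >= 0
  c1 <- mean(a[inside]); c2 <- mean(a[!inside])
  h <- 0.5 * (1 + (2 / pi) * atan(p / eps))
  tv <- 0
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    gx <- if (i < 3) h[i + 1, j, k] - h[i, j, k] else 0
    gy <- if (j < 3) h[i, j + 1, k] - h[i, j, k] else 0
    gz <- if (k < 3) h[i, j, k + 1] - h[i, j, k] else 0
    tv <- tv + sqrt(gx^2 + gy^2 + gz^2)
  }
  want <- mu * tv + sum((a[inside] - c1)^2) + sum((a[!inside] - c2)^2)
  expect_equal(chan_vese_energy(a, p, mu, eps), want, tolerance = 1e-10)
})

test_that("the monitored energy is non-increasing on arbitrary inputs", {
  for (seed in c(1, 2)) {
    img <- abs(rand_field(c(16, 16, 8), seed)) / 3
    init <- array(0L, c(16, 16, 8)); init[5:12, 5:12, 3:6] <- 1L
    seg <- chan_vese_segment(img, init, chan_vese_config(max_iter = 40))
    e0 <- seg$energy[1]
    expect_true(all(diff(seg$energy) <= 1e-8 * e0))
  }
})

test_that("a clean two-intensity phantom is segmented exactly from a dilated init", {
  sp <- phantom_spec(shape = c(32L, 32L, 16L), noise_sigma = 0,
                     background_intensity = 0.7)
  ph <- make_phantom(sp)
  truth <- ph$labels_target$labels > 0
  init <- lsreg:::binary_dilate(truth, 2)
  seg <- chan_vese_segment(normalize_intensities(ph$target), init + 0,
                           chan_vese_config(max_iter = 600))
  expect_equal(dice(seg$labels$labels, truth + 0), 1.0)
  expect_false(seg$collapsed)
})

test_that("segmentation is invariant to affine intensity changes after normalization", {
  sp <- phantom_spec(shape = c(24L, 24L, 12L), noise_sigma = 0.01,
                     background_intensity = 0.7)
  ph <- make_phantom(sp)
  img <- ph$target$values
  init <- (ph$labels_target$labels > 0) + 0L
  cfg <- chan_vese_config(max_iter = 60)
  a <- chan_vese_segment(normalize_intensities(img), init, cfg)
  b <- chan_vese_segment(normalize_intensities(3.5 * img + 11), init, cfg)
  expect_equal(normalize_intensities(3.5 * img + 11), normalize_intensities(img),
               tolerance = 1e-12)
  expect_equal(a$labels$labels, b$labels$labels)
})

test_that("a uniform image leaves the region forces inert and flags collapse only when a side empties", {
  img <- array(0.5, c(12, 12, 6))
  init <- array(0L, c(12, 12, 6)); init[4:9, 4:9, 2:5] <- 1L
  seg <- chan_vese_segment(img, init, chan_vese_config(max_iter = 20))
  # c1 = c2 makes the data term vanish; only curvature acts on the contour
  expect_true(all(diff(seg$energy) <= 1e-8 * seg$energy[1]))
  expect_true(all(seg$labels$labels %in% c(0L, 1L)))
})
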