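test_that("block downsampling averages factor^3 blocks, truncated at edges", {
  const <- array(0.4, c(8, 8, 4))
  expect_equal(downsample(const, 2), array(0.4, c(4, 4, 2)))
  a <- rand_field(c(8, 8, 8), seed = 81)
  expect_equal(downsample(a, 2), oracle_block_mean(a, 2))
  expect_equal(downsample(a, 4), oracle_block_mean(a, 4))
  # non-divisible shape: edge blocks average the available voxels
  b <- rand_field(c(7, 5, 3), seed = 82)
  expect_equal(downsample(b, 2), oracle_block_mean(b, 2))
  expect_equal(dim(downsample(array(0, c(256, 256, 108)), 4)), c(64L, 64L, 27L))
  # commutes with affine intensity maps
  expect_equal(downsample(2 * a + 1, 2), 2 * downsample(a, 2) + 1)
  expect_error(downsample(a, 0), "positive")
})

test_that("label downsampling is a per-block majority vote with integral output", {
  lab <- array(0L, c(8, 8, 4))
  lab[1:5, 1:8, ] <- 1L  # x-blocks 1..2 mostly label 1 at factor 4? block 2 has 1 of 4
  got <- downsample_labels(lab, 4)
  expect_true(all(got %in% c(0L, 1L)))
  expect_equal(got[1, 1, 1], 1L)  # block x 1:4 fully label 1
  expect_equal(got[2, 1, 1], 0L)  # block x 5:8 has one labelled slab out of four
  two <- toy_two_region_labels()
  d2 <- downsample_labels(two, 2)
  expect_true(all(sort(unique(as.vector(d2))) %in% c(0L, 1L, 2L)))
  expect_equal(dim(d2), as.integer(ceiling(dim(two) / 2)))
})

test_that("displacement upsampling rescales voxel units and is exact on linear fields", {
  z <- array(0, c(4, 4, 2, 3))
  up <- upsample_displacement(z, 2, c(8, 8, 4))
  expect_equal(up, array(0, c(8, 8, 4, 3)))
  cst <- z; cst[, , , 1] <- 1
  upc <- upsample_displacement(cst, 2, c(8, 8, 4))
  expect_equal(upc[, , , 1], array(2, c(8, 8, 4)))
  expect_equal(upc[, , , 2:3], array(0, c(8, 8, 4, 2)))
  # linear coarse component -> exact linear fine component (x factor)
  dc <- c(6, 5, 4)
  co <- expand.grid(x = 0:(dc[1] - 1), y = 0:(dc[2] - 1), z = 0:(dc[3] - 1))
  lin <- z0 <- array(0, c(dc, 3))
  lin[, , , 2] <- array(0.2 * co$x - 0.1 * co$y + 0.05 * co$z, dc)
  fine <- c(12, 10, 8)
  upl <- upsample_displacement(lin, 2, fine)
  cof <- expand.grid(x = 0:(fine[1] - 1), y = 0:(fine[2] - 1), z = 0:(fine[3] - 1))
  # fine coordinate maps to coarse block-center coordinate (x - 1/2) / 2,
  # clamped to the coarse domain where the fine grid extends past it
  cl <- function(v, n) pmin(pmax(v, 0), n - 1)
  want <- 2 * (0.2 * cl((cof$x - 0.5) / 2, dc[1]) -
               0.1 * cl((cof$y - 0.5) / 2, dc[2]) +
               0.05 * cl((cof$z - 0.5) / 2, dc[3]))
  expect_equal(as.vector(upl[, , , 2]), want, tolerance = 1e-12)
})

test_that("warm-started fine level opens at or below the cold-start residual", {
  ph <- make_phantom(phantom_spec(shape = c(32L, 32L, 16L), seed = 8))
  tgt <- normalize_intensities(ph$target)
  src <- normalize_intensities(ph$source)
  cfg <- registration_config(variant = "gcv1+vem", gamma = 1.5, max_iter = 40L)
  coarse <- register_single_level(downsample(src$values, 2), downsample(tgt$values, 2),
                                  downsample_labels(ph$labels_target$labels, 2),
                                  cfg)
  u0 <- upsample_displacement(coarse$u, 2, dim(tgt$values))
  # measured on the sigma1-smoothed images the evolution actually matches
  # (the raw residual is dominated by the independent voxel noise)
  s_sm <- gaussian_smooth(src$values, cfg$sigma1)
  t_sm <- gaussian_smooth(tgt$values, cfg$sigma1)
  resid_cold <- mean(abs(t_sm - s_sm))
  resid_warm <- mean(abs(t_sm - lsreg:::warp_scalar(s_sm, u0)))
  expect_lte(resid_warm, resid_cold)
})

test_that("the multilevel driver matches identical inputs with a near-zero field", {
  ph <- make_phantom(phantom_spec(shape = c(24L, 24L, 12L), seed = 9, noise_sigma = 0))
  img <- normalize_intensities(ph$target)
  r <- register_multilevel(img, img, ph$labels_target,
                           registration_config(variant = "vem_only"))
  expect_lt(max(abs(r$u)), 1e-10)
})
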