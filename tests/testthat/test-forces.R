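test_that("sign bands cover exactly the gamma-neighbourhood of the region boundary", {
  lab <- array(0L, c(16, 16, 16))
  lab[5:10, 5:10, 5:10] <- 1L  # solid cube
  gamma <- 2.5
  band <- make_sign_band(lab, gamma, 1L)
  expect_true(all(band$values %in% c(-1, 0)))
  # boundary voxel of the cube carries the orientation constant -1
  expect_equal(band$values[5, 7, 7], -1)
  # far voxel is outside the band
  expect_equal(band$values[16, 16, 16], 0)
  # support equals the exhaustive distance transform of the boundary set
  b <- lsreg:::boundary_voxels(lab == 1L)
  want <- oracle_distance2(b) <= gamma^2
  expect_equal(band$values != 0, want)
  expect_error(make_sign_band(array(0L, c(4, 4, 4)), 2, 1L), "empty")
})

test_that("fixed region means reproduce hand-computed averages and stay immutable inputs", {
  lab <- array(c(1L, 1L, 0L, 0L, 2L, 2L, 0L, 0L, 0L), c(3, 3, 1))
  tgt <- array(c(0.2, 0.4, 0.9, 0.7, 0.1, 0.3, 0.8, 0.6, 1.0), c(3, 3, 1))
  m2 <- region_means_fixed(tgt, lab, "two_region")
  expect_equal(m2$c_in, mean(c(0.2, 0.4, 0.1, 0.3)))
  expect_equal(m2$c_out, mean(c(0.9, 0.7, 0.8, 0.6, 1.0)))
  m4 <- region_means_fixed(tgt, lab, "four_region")
  expect_equal(m4$c_in1, 0.3)
  expect_equal(m4$c_in2, 0.2)
  expect_equal(m4$c_out1, m4$c_out2)
  # piecewise-constant target matching the labels -> the constants themselves
  lab2 <- toy_two_region_labels()
  tgt2 <- array(0.7, dim(lab2)); tgt2[lab2 > 0] <- 0.2
  mm <- region_means_fixed(tgt2, lab2, "four_region")
  expect_equal(c(mm$c_in1, mm$c_in2, mm$c_out1), c(0.2, 0.2, 0.7))
  u <- array(0.5, dim(lab2))
  mu_ <- region_means_fixed(u, lab2, "two_region")
  expect_equal(mu_$c_in, mu_$c_out)
  expect_error(region_means_fixed(tgt, array(0L, dim(tgt)), "two_region"), "empty")
})

test_that("the Vemuri force vanishes on matched or flat inputs and matches the oracle", {
  d <- c(6, 6, 6)
  a <- abs(rand_field(d, 51))
  expect_equal(vemuri_force(a, a, NULL), array(0, c(d, 3)))
  flat <- array(0.4, d)
  tgt <- rand_field(d, 52)
  expect_equal(vemuri_force(tgt, flat, NULL), array(0, c(d, 3)))
  src <- abs(rand_field(d, 53))
  got <- vemuri_force(tgt, src, NULL, alpha = 1e-4)
  want <- oracle_vemuri(tgt, src, array(0, c(d, 3)), 1e-4)
  expect_equal(got, want, tolerance = 1e-12)
  # and with a nonzero displacement
  u <- array(0.3 * sin(seq_len(prod(d) * 3)), c(d, 3))
  expect_equal(vemuri_force(tgt, src, u, 1e-4), oracle_vemuri(tgt, src, u, 1e-4),
               tolerance = 1e-12)
})

test_that("GCV forces are band-limited, cancel at the mean midpoint, and decompose per region", {
  lab <- toy_two_region_labels()
  d <- dim(lab)
  tgt <- array(0.7, d); tgt[lab > 0] <- 0.2
  atlas1 <- smoothed_atlas(lab, sigma2 = 1.5, variant = 1)
  means1 <- region_means_fixed(tgt, lab, "two_region")
  band <- make_sign_band(lab, 1.5, NULL)
  src <- tgt + 0.05 * rand_field(d, 61)
  f1 <- gcv_force(1, src, NULL, atlas1, means1, band)
  outside <- band$values == 0
  for (cc in 1:3) expect_true(all(f1[, , , cc][outside] == 0))
  # source exactly at the midpoint of the two means -> algebraic cancellation
  mid <- array((means1$c_in + means1$c_out) / 2, d)
  expect_equal(gcv_force(1, mid, NULL, atlas1, means1, band), array(0, c(d, 3)))
  # variant 3 equals the sum of two independent single-region variant-1 terms
  atlas3 <- smoothed_atlas(lab, sigma2 = 1.5, variant = 3)
  means4 <- region_means_fixed(tgt, lab, "four_region")
  bands3 <- list(make_sign_band(lab, 1.5, 1L), make_sign_band(lab, 1.5, 2L))
  f3 <- gcv_force(3, src, NULL, atlas3, means4, bands3)
  per_region <- array(0, c(d, 3))
  for (r in 1:2) {
    lab_r <- array(0L, d); lab_r[lab == r] <- 1L
    atlas_r <- smoothed_atlas(lab_r, sigma2 = 1.5, variant = 1)
    means_r <- list(c_in = means4[[paste0("c_in", r)]], c_out = means4$c_out1)
    per_region <- per_region +
      gcv_force(1, src, NULL, atlas_r, means_r, bands3[[r]])
  }
  expect_equal(f3, per_region, tolerance = 1e-12)
  # overlapping bands violate the strong-disjointness precondition
  wide <- list(make_sign_band(lab, 5, 1L), make_sign_band(lab, 5, 2L))
  expect_error(gcv_force(3, src, NULL, atlas3, means4, wide), "disjoint")
})

test_that("the band velocity pulls samples toward the contour crossing", {
  # outside-like samples (closer to c_out) move along the inward atlas
  # gradient; inside-like samples move outward — both toward the
  # (c_in + c_out)/2 crossing, the stationary configuration of the velocity
  lab <- array(0L, c(16, 10, 8)); lab[4:8, 3:7, 3:6] <- 1L
  tgt <- array(0.8, dim(lab)); tgt[lab > 0] <- 0.2
  atlas <- smoothed_atlas(lab, sigma2 = 1.5, variant = 1)
  means <- region_means_fixed(tgt, lab, "two_region")
  band <- make_sign_band(lab, 1.5, NULL)
  inward <- atlas$regions[[1]]$grad  # gradient of the indicator points inward
  for (src_val in c(0.75, 0.25)) {  # outside-like, inside-like
    f <- gcv_force(1, array(src_val, dim(lab)), NULL, atlas, means, band)
    dots <- apply(f * inward, 1:3, sum)
    sel <- band$values != 0 & apply(inward^2, 1:3, sum) > 1e-6
    if ((src_val - means$c_in)^2 > (src_val - means$c_out)^2) {
      expect_true(all(dots[sel] > 0))   # pulled inward
    } else {
      expect_true(all(dots[sel] < 0))   # pushed outward
    }
  }
})

test_that("the GCV1 force matches a nodewise brute-force composition", {
  lab <- array(0L, c(8, 8, 6)); lab[3:6, 3:6, 2:5] <- 1L
  tgt <- array(0.75, dim(lab)); tgt[lab > 0] <- 0.25
  src <- tgt + 0.1 * rand_field(dim(lab), 71)
  atlas <- smoothed_atlas(lab, sigma2 = 1, variant = 1, alpha = 1e-4)
  means <- region_means_fixed(tgt, lab, "two_region")
  band <- make_sign_band(lab, 2, NULL)
  u <- 0.4 * array(cos(seq_len(prod(dim(lab)) * 3)), c(dim(lab), 3))
  got <- gcv_force(1, src, u, atlas, means, band, alpha = 1e-4)
  want <- oracle_gcv1(src, u, atlas$regions[[1]]$grad, band$values,
                      means$c_in, means$c_out, 1e-4)
  expect_equal(got, want, tolerance = 1e-12)
})
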