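# Synthetic thorax phantom: paired "inhale/exhale" volumes with two dark
# lung-like ellipsoids inside a brighter body ellipsoid, a smooth
# breathing-like deformation (sum of Gaussian bumps), seeded noise, and
# paired landmarks inside the lungs — a desk-scale stand-in for a 4D-CT
# lung pair with expert landmarks.

#' Phantom specification
#'
#' Geometry, intensities, deformation and sampling parameters of the
#' synthetic thorax phantom. Defaults: a 64x64x32 grid with anisotropic
#' spacing (1, 1, 2.5) mm, body intensity 0.7, lung intensity 0.2,
#' background 0, two lung ellipsoids separated by more than twice the
#' default band width, two Gaussian displacement bumps per lung (amplitude
#' at most 4 voxels, width 8 voxels), additive Gaussian noise of sd 0.02,
#' and 50 landmarks.
#'
#' @param shape grid shape (3 positive integers).
#' @param spacing voxel spacing in mm.
#' @param body_intensity,lung_intensity,background_intensity intensities in
#'   \[0, 1\].
#' @param body_center,body_semiaxes body ellipsoid, voxel units (0-based).
#' @param lung_centers list of two lung ellipsoid centers.
#' @param lung_semiaxes list of two lung semi-axis triples.
#' @param bumps optional data.frame of deformation bumps with columns `cx`,
#'   `cy`, `cz` (center), `ax`, `ay`, `az` (amplitude vector, voxels) and
#'   `width` (Gaussian std-dev, voxels); `NULL` draws two bumps per lung
#'   from the seed.
#' @param noise_sigma additive Gaussian noise sd.
#' @param n_landmarks number of paired landmarks sampled inside the lungs.
#' @param seed RNG seed making the phantom fully deterministic.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 32L), spacing = c(1, 1, 2.5),
                         body_intensity = 0.7, lung_intensity = 0.2,
                         background_intensity = 0,
                         body_center = (shape - 1) / 2,
                         body_semiaxes = c(0.45, 0.45, 0.45) * shape,
                         lung_centers = list(
                           c(0.305, 0.5, 0.5) * (shape - 1),
                           c(0.695, 0.5, 0.5) * (shape - 1)),
                         lung_semiaxes = list(
                           c(0.125, 0.17, 0.25) * shape,
                           c(0.125, 0.17, 0.25) * shape),
                         bumps = NULL, noise_sigma = 0.02,
                         n_landmarks = 50L, seed = 1234L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 4L),
            noise_sigma >= 0, n_landmarks >= 0)
  structure(list(shape = shape, spacing = rep_len(as.numeric(spacing), 3L),
                 body_intensity = body_intensity,
                 lung_intensity = lung_intensity,
                 background_intensity = background_intensity,
                 body_center = body_center, body_semiaxes = body_semiaxes,
                 lung_centers = lung_centers, lung_semiaxes = lung_semiaxes,
                 bumps = bumps, noise_sigma = noise_sigma,
                 n_landmarks = as.integer(n_landmarks),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

in_ellipsoid <- function(p, center, semi) {
  rowSums(sweep(sweep(p, 2L, center), 2L, semi, `/`)^2) <= 1
}

# Region id (0 background/body, 1/2 lungs) at continuous points.
phantom_region_at <- function(spec, p) {
  out <- rep.int(0L, nrow(p))
  out[in_ellipsoid(p, spec$lung_centers[[1L]], spec$lung_semiaxes[[1L]])] <- 1L
  out[in_ellipsoid(p, spec$lung_centers[[2L]], spec$lung_semiaxes[[2L]])] <- 2L
  out
}

phantom_intensity_at <- function(spec, p) {
  out <- rep.int(spec$background_intensity, nrow(p))
  out[in_ellipsoid(p, spec$body_center, spec$body_semiaxes)] <- spec$body_intensity
  region <- phantom_region_at(spec, p)
  out[region > 0L] <- spec$lung_intensity
  out
}

# Analytic deformation: u(p) = sum_b a_b * exp(-|p - c_b|^2 / (2 w_b^2)).
phantom_displacement_at <- function(bumps, p) {
  out <- matrix(0, nrow(p), 3L)
  for (i in seq_len(nrow(bumps))) {
    e <- exp(-rowSums(sweep(p, 2L, c(bumps$cx[i], bumps$cy[i], bumps$cz[i]))^2) /
               (2 * bumps$width[i]^2))
    out <- out + outer(e, c(bumps$ax[i], bumps$ay[i], bumps$az[i]))
  }
  out
}

# Invert y = x + u(x) by fixed-point iteration (the bump field is a
# contraction: amplitude/width keeps the displacement Jacobian below 1).
phantom_invert_warp <- function(bumps, y, iters = 30L) {
  x <- y
  for (i in seq_len(iters)) {
    x <- y - phantom_displacement_at(bumps, x)
  }
  x
}

draw_default_bumps <- function(spec) {
  sc <- min(1, min(spec$shape) / 32)  # shrink bumps with the grid
  rows <- list()
  for (l in 1:2) {
    ctr <- spec$lung_centers[[l]]
    semi <- spec$lung_semiaxes[[l]]
    for (b in 1:2) {
      c_b <- ctr + runif(3, -0.4, 0.4) * semi
      dir <- c(runif(2, -0.4, 0.4), runif(1, 0.6, 1))  # mostly axial, breathing-like
      dir <- dir / sqrt(sum(dir^2))
      mag <- runif(1, 2, 3.5) * sc
      rows[[length(rows) + 1L]] <- data.frame(
        cx = c_b[1], cy = c_b[2], cz = c_b[3],
        ax = mag * dir[1], ay = mag * dir[2], az = mag * dir[3],
        width = 8 * sc)
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic thorax phantom pair
#'
#' Builds the target volume (piecewise-constant thorax plus seeded Gaussian
#' noise), the ground-truth displacement field on the target grid, the
#' source volume (the noiseless analytic target resampled through the warp,
#' with independent noise), analytic warped lung masks for the source,
#' and paired landmarks sampled uniformly inside the lungs. Fully
#' deterministic for a given spec and seed.
#'
#' The displacement convention matches the registration's: `u` maps target
#' coordinates into source space, so `I_S(x + u(x)) = I_T(x)` holds for the
#' noiseless images (up to the voxel rasterization of the landmarks and
#' masks).
#'
#' @param spec a [phantom_spec()].
#' @return a `lsreg_phantom` list with fields `target`, `source`
#'   ([image_volume()]s), `labels_target`, `labels_source_truth`
#'   ([label_map()]s; 1 = left lung, 2 = right lung), `landmarks`
#'   ([landmark_set()]), `u_truth` (4-D array, voxel units), `bumps` and
#'   `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  pts <- grid_coordinates(d)
  bumps <- if (is.null(spec$bumps)) draw_default_bumps(spec) else spec$bumps

  labels_target <- array(phantom_region_at(spec, pts), d)
  target_clean <- array(phantom_intensity_at(spec, pts), d)
  u_grid <- phantom_displacement_at(bumps, pts)
  u_truth <- array(0, c(d, 3L))
  for (cc in 1:3) u_truth[, , , cc] <- u_grid[, cc]

  # invariants: no topology change, strongly disjoint lungs
  max_amp <- max(sqrt(rowSums(u_grid^2)))
  min_semi <- min(unlist(spec$lung_semiaxes))
  if (max_amp >= min_semi) {
    stop(sprintf("deformation amplitude %.2f exceeds min lung semi-axis %.2f",
                 max_amp, min_semi), call. = FALSE)
  }
  m1 <- labels_target == 1L
  m2 <- labels_target == 2L
  if (!any(m1) || !any(m2)) stop("a lung region rasterized to empty", call. = FALSE)
  gamma_ref <- 3 * min(1, min(d) / 32)  # default band width at this grid scale
  sep <- sqrt(min(edt_squared(m1)[m2]))
  if (sep <= 2 * gamma_ref) {
    stop(sprintf("lung separation %.2f voxels is not > 2 * band width (%.2f)",
                 sep, 2 * gamma_ref), call. = FALSE)
  }

  # source: noiseless analytic target resampled through the warp,
  # I_S(y) = I_T(U^{-1}(y)); warped masks from the same analytic inverse
  x_inv <- phantom_invert_warp(bumps, pts)
  source_clean <- array(phantom_intensity_at(spec, x_inv), d)
  labels_source <- array(phantom_region_at(spec, x_inv), d)

  target_vals <- target_clean
  source_vals <- source_clean
  if (spec$noise_sigma > 0) {
    target_vals <- target_vals + array(rnorm(prod(d), 0, spec$noise_sigma), d)
    source_vals <- source_vals + array(rnorm(prod(d), 0, spec$noise_sigma), d)
  }

  lung_idx <- which(labels_target > 0L)
  n_lm <- min(spec$n_landmarks, length(lung_idx))
  lm_idx <- if (n_lm > 0) sample(lung_idx, n_lm) else integer(0)
  y <- pts[lm_idx, , drop = FALSE]
  x <- round(y + phantom_displacement_at(bumps, y))
  for (ax in 1:3) x[, ax] <- pmin(pmax(x[, ax], 0), d[ax] - 1L)

  structure(list(
    target = image_volume(target_vals, spec$spacing),
    source = image_volume(source_vals, spec$spacing),
    labels_target = label_map(labels_target, spec$spacing),
    labels_source_truth = label_map(labels_source, spec$spacing),
    landmarks = landmark_set(target = y, source = x, spacing = spec$spacing),
    u_truth = u_truth, bumps = bumps, spec = spec),
    class = "lsreg_phantom")
}

#' @export
print.lsreg_phantom <- function(x, ...) {
  cat(sprintf("<lsreg_phantom> %s grid, %d landmarks, %d deformation bumps, seed %d\n",
              paste(x$spec$shape, collapse = "x"), nrow(x$landmarks$target),
              nrow(x$bumps), x$spec$seed))
  invisible(x)
}
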