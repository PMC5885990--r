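# Displacement-driving vector fields: the intensity-driven Vemuri force and
# the three segmentation-driven narrow-band (GCV) forces, together with the
# sign bands and fixed region means they require.
#
# Conventions: the prior label map lives on the target grid; its smoothed
# indicator(s) and their minmod gradients are precomputed once (they do not
# change in time) and the gradient is *interpolated* at the warped position
# U(x) = x + u(x) rather than re-differentiated.

#' Narrow-band sign function around a region boundary
#'
#' Builds the modified sign function `S(x)` that is a nonzero constant only
#' within Euclidean distance `gamma` of the region's discrete boundary and 0
#' elsewhere. With the indicator convention (label function 1 inside the
#' region), the smoothed-atlas gradient points inward, so the constant is -1:
#' `S * grad(G_sigma2 * phi_L)` then points from the region interior to the
#' exterior.
#'
#' @param labels [label_map()] or integer array.
#' @param gamma band half-width in voxels (> 0).
#' @param region_id region label forming the band; `NULL` (default) takes the
#'   union of all nonzero labels.
#' @return a `sign_band` list with `values` (array in \{-1, 0\}), `gamma` and
#'   `region_id`.
#' @export
make_sign_band <- function(labels, gamma, region_id = NULL) {
  stopifnot(gamma > 0)
  lab <- as_field3d(labels)
  mask <- if (is.null(region_id)) lab > 0 else lab == region_id
  if (!any(mask)) stop("region is empty; cannot build a sign band", call. = FALSE)
  if (all(mask)) stop("region covers the whole grid; it has no boundary", call. = FALSE)
  b <- boundary_voxels(mask)
  band <- edt_squared(b) <= gamma^2
  structure(list(values = -(band + 0), gamma = gamma, region_id = region_id),
            class = "sign_band")
}

#' Fixed region means of the target image under the prior labels
#'
#' Voxel-count-weighted mean target intensities per region. These are
#' computed once, before the evolution starts, and kept constant throughout
#' the registration. The `four_region` variant returns means over the two
#' labeled regions (labels 1 and 2) plus a shared outside mean over the
#' complement (the part of the image not occupied by either region).
#'
#' @param target target image ([image_volume()] or array).
#' @param labels prior [label_map()] on the same grid.
#' @param variant `"two_region"` (inside = any nonzero label) or
#'   `"four_region"` (labels 1 and 2 separately).
#' @return a `region_means_fixed` list: `c_in`/`c_out` for two_region;
#'   `c_in1`, `c_in2`, `c_out1`, `c_out2` (the last two equal) for
#'   four_region.
#' @export
region_means_fixed <- function(target, labels,
                               variant = c("two_region", "four_region")) {
  variant <- match.arg(variant)
  a <- as_field3d(target)
  lab <- as_field3d(labels)
  check_same_grid(a, lab, "target and labels")
  mean_over <- function(mask, what) {
    if (!any(mask)) stop(sprintf("region '%s' is empty", what), call. = FALSE)
    sum(a[mask]) / sum(mask)
  }
  out_mask <- lab == 0
  if (variant == "two_region") {
    m <- list(c_in = mean_over(lab > 0, "inside"),
              c_out = mean_over(out_mask, "outside"))
  } else {
    c_out <- mean_over(out_mask, "outside")
    m <- list(c_in1 = mean_over(lab == 1, "region 1"),
              c_in2 = mean_over(lab == 2, "region 2"),
              c_out1 = c_out, c_out2 = c_out)
  }
  structure(c(m, list(variant = variant)), class = "region_means_fixed")
}

#' Smoothed atlas level-set(s) and their stationary gradients
#'
#' Precomputes `G_sigma2 * phi_L` for the prior label map and the minmod
#' gradient of the smoothed field(s). For the single-atlas forces (GCV1,
#' GCV2) one field is built from the indicator of the union of labeled
#' regions; for the multi-region force (GCV3) one indicator per region label
#' (1 and 2). These fields are independent of time, so their gradients are
#' computed once and later interpolated at warped positions.
#'
#' @param labels prior [label_map()].
#' @param sigma2 atlas smoothing standard deviation in voxels.
#' @param variant force variant (1, 2 or 3).
#' @param alpha norm regularizer.
#' @return a `smoothed_atlas` list; field `regions` is a list (length 1 or 2)
#'   each with `phi_smooth`, `grad` (4-D) components.
#' @export
smoothed_atlas <- function(labels, sigma2, variant = 1, alpha = 1e-4) {
  lab <- as_field3d(labels)
  ids <- if (variant == 3) list(1, 2) else list(NULL)
  regions <- lapply(ids, function(id) {
    ind <- if (is.null(id)) (lab > 0) + 0 else (lab == id) + 0
    if (!any(ind > 0)) stop("atlas region is empty", call. = FALSE)
    sm <- gaussian_smooth(ind, sigma2)
    list(region_id = id, phi_smooth = sm, grad = minmod_gradient(sm, alpha)$grad)
  })
  structure(list(regions = regions, sigma2 = sigma2, variant = variant,
                 alpha = alpha), class = "smoothed_atlas")
}

# Interpolate a stationary 4-D gradient field at the warped positions
# x + u(x); returns list(grad = 4-D array, norm = alpha-regularized norm).
warp_gradient <- function(grad, u, alpha) {
  d <- dim(grad)[1:3]
  pts <- grid_coordinates(d)
  pts[, 1L] <- pts[, 1L] + as.vector(u[, , , 1L])
  pts[, 2L] <- pts[, 2L] + as.vector(u[, , , 2L])
  pts[, 3L] <- pts[, 3L] + as.vector(u[, , , 3L])
  g <- array(0, dim(grad))
  nsq <- array(alpha^2, d)
  for (cc in 1:3) {
    gc <- array(interpolate(grad[, , , cc], pts), d)
    g[, , , cc] <- gc
    nsq <- nsq + gc * gc
  }
  list(grad = g, norm = sqrt(nsq))
}

#' Vemuri intensity-driven force
#'
#' The level-set registration force
#' `(I_T - I_S(U(x))) * grad(I_S(U(x))) / |grad(I_S(U(x)))|_alpha`,
#' where the warped source `I_S(U(x))` is obtained by trilinear interpolation
#' at `U(x) = x + u(x)` and its gradient by the minmod scheme on the warped
#' samples. The alpha-regularized norm keeps the force finite everywhere.
#'
#' @param I_T target image (array or [image_volume()]), normalized (and
#'   typically pre-smoothed).
#' @param I_S source image on the same grid.
#' @param u displacement field, 4-D array (voxel units); `NULL` for zero.
#' @param alpha norm regularizer.
#' @return 4-D force array (last dimension = component).
#' @export
vemuri_force <- function(I_T, I_S, u = NULL, alpha = 1e-4) {
  t_arr <- as_field3d(I_T)
  s_arr <- as_field3d(I_S)
  check_same_grid(t_arr, s_arr, "target and source")
  d <- dim(t_arr)
  if (is.null(u)) u <- zero_displacement(d)
  check_same_grid(t_arr, u, "images and displacement")
  warped <- warp_scalar(s_arr, u)
  g <- minmod_gradient(warped, alpha)
  resid <- t_arr - warped
  out <- g$grad
  for (cc in 1:3) out[, , , cc] <- resid * g$grad[, , , cc] / g$norm
  out
}

#' Segmentation-driven narrow-band (GCV) force
#'
#' The atlas-based force `-S(x) * B(I_S(U(x))) * grad(G*phi_L)(U(x)) /
#' |grad(G*phi_L)(U(x))|_alpha`, zero outside the narrow sign band(s).
#' The bracket `B` compares the warped source intensity with the fixed
#' region means of the target:
#' \describe{
#'   \item{variant 1}{`(I - c_in)^2 - (I - c_out)^2` with one atlas field
#'     (union of labeled regions).}
#'   \item{variant 2}{the four-mean bracket `(I - c_in1)^2 - (I - c_out1)^2 +
#'     (I - c_in2)^2 - (I - c_out2)^2`, same single direction field.}
#'   \item{variant 3}{the sum of two independent single-region terms, each
#'     with its own band, indicator and two-mean bracket; requires the two
#'     regions to be strongly disjoint (separation `> 2*gamma`) so the terms
#'     cannot influence each other.}
#' }
#'
#' @param variant 1, 2 or 3.
#' @param I_S source image.
#' @param u displacement field (4-D array) or `NULL` for zero.
#' @param atlas a [smoothed_atlas()] built with the matching variant.
#' @param means a [region_means_fixed()] (`two_region` for variant 1,
#'   `four_region` for variants 2 and 3).
#' @param bands a [make_sign_band()] (variants 1, 2) or list of two (variant 3).
#' @param alpha norm regularizer.
#' @return 4-D force array.
#' @export
gcv_force <- function(variant, I_S, u, atlas, means, bands, alpha = 1e-4) {
  stopifnot(variant %in% 1:3)
  s_arr <- as_field3d(I_S)
  d <- dim(s_arr)
  if (is.null(u)) u <- zero_displacement(d)
  if (inherits(bands, "sign_band")) bands <- list(bands)
  if (variant == 3 && length(bands) != 2L) {
    stop("variant 3 needs one sign band per region", call. = FALSE)
  }
  if (variant == 3 && any(bands[[1]]$values != 0 & bands[[2]]$values != 0)) {
    stop("sign-band supports overlap: regions are not strongly disjoint (need separation > 2*gamma)",
         call. = FALSE)
  }
  warped <- warp_scalar(s_arr, u)
  brackets <- switch(as.character(variant),
    "1" = list((warped - means$c_in)^2 - (warped - means$c_out)^2),
    "2" = list((warped - means$c_in1)^2 - (warped - means$c_out1)^2 +
               (warped - means$c_in2)^2 - (warped - means$c_out2)^2),
    "3" = list((warped - means$c_in1)^2 - (warped - means$c_out1)^2,
               (warped - means$c_in2)^2 - (warped - means$c_out2)^2))
  out <- zero_displacement(d)
  for (r in seq_along(brackets)) {
    s_vals <- bands[[r]]$values
    if (all(s_vals == 0)) next
    wg <- warp_gradient(atlas$regions[[r]]$grad, u, alpha)
    scal <- -s_vals * brackets[[r]] / wg$norm
    for (cc in 1:3) out[, , , cc] <- out[, , , cc] + scal * wg$grad[, , , cc]
  }
  out
}
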