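# Coarse-to-fine driver: quarter -> half -> full resolution. Coarse images
# are non-overlapping block means (box averaging), label maps are
# downsampled by majority vote, and each level warm-starts from the
# upsampled displacement of the previous one.

#' Block-average downsampling
#'
#' Averages the image over non-overlapping `factor`^3 blocks (convolution
#' with a box function sampled at the coarser grid). Edge blocks whose shape
#' is not divisible by the factor are averaged over the available voxels.
#'
#' @param image [image_volume()] or array.
#' @param factor integer downsampling factor (2 or 4); 1 returns the input.
#' @return same type as input, at shape `ceiling(dim / factor)`.
#' @export
downsample <- function(image, factor) {
  if (factor < 1) stop("`factor` must be a positive integer", call. = FALSE)
  factor <- as.integer(factor)
  a <- as_field3d(image)
  if (factor == 1L) {
    return(if (inherits(image, "image_volume")) image_volume(a, image$spacing) else a)
  }
  d <- dim(a)
  dc <- as.integer(ceiling(d / factor))
  grp <- block_groups(d, dc, factor)
  sums <- rowsum(as.vector(a), grp, reorder = TRUE)
  cnts <- rowsum(rep(1, length(a)), grp, reorder = TRUE)
  out <- array(as.vector(sums / cnts), dc)
  if (inherits(image, "image_volume")) {
    image_volume(out, image$spacing * factor)
  } else {
    out
  }
}

# Coarse-block linear index (1-based) of every fine voxel, in array order.
block_groups <- function(d, dc, factor) {
  cx <- (seq_len(d[1L]) - 1L) %/% factor
  cy <- (seq_len(d[2L]) - 1L) %/% factor
  cz <- (seq_len(d[3L]) - 1L) %/% factor
  1L + rep.int(cx, d[2L] * d[3L]) +
    dc[1L] * (rep.int(rep(cy, each = d[1L]), d[3L]) +
              dc[2L] * rep(cz, each = d[1L] * d[2L]))
}

#' Majority-vote label downsampling
#'
#' Assigns each coarse block the most frequent label among its fine voxels;
#' ties are broken toward the smaller label id. Keeps labels integral, which
#' block averaging would not.
#'
#' @param labels [label_map()] or integer array.
#' @param factor integer downsampling factor.
#' @return same type as input.
#' @export
downsample_labels <- function(labels, factor) {
  if (factor < 1) stop("`factor` must be a positive integer", call. = FALSE)
  factor <- as.integer(factor)
  lab <- as_field3d(labels)
  if (factor == 1L) {
    return(if (inherits(labels, "label_map")) label_map(lab, labels$spacing) else lab)
  }
  d <- dim(lab)
  dc <- as.integer(ceiling(d / factor))
  grp <- block_groups(d, dc, factor)
  ids <- sort(unique(as.vector(lab)))
  best_count <- rep(-1, prod(dc))
  best_label <- rep(0L, prod(dc))
  for (l in ids) {
    cnt <- rowsum((as.vector(lab) == l) + 0, grp, reorder = TRUE)
    take <- as.vector(cnt) > best_count  # strict: ties keep the smaller id
    best_count[take] <- as.vector(cnt)[take]
    best_label[take] <- l
  }
  out <- array(best_label, dc)
  if (inherits(labels, "label_map")) {
    label_map(out, labels$spacing * factor)
  } else {
    out
  }
}

#' Upsample a displacement field to a finer grid
#'
#' Trilinearly interpolates each component at the fine-grid positions mapped
#' into coarse block-center coordinates, then multiplies by `factor` to
#' rescale voxel units. A fine coordinate `x` corresponds to the coarse
#' coordinate `(x - (factor - 1) / 2) / factor` (block centers).
#'
#' @param u_coarse coarse displacement (4-D array, coarse voxel units).
#' @param factor integer upsampling factor.
#' @param fine_shape length-3 integer target grid shape.
#' @return 4-D displacement on the fine grid, in fine voxel units.
#' @export
upsample_displacement <- function(u_coarse, factor, fine_shape) {
  factor <- as.integer(factor)
  fine_shape <- as.integer(fine_shape)
  if (factor == 1L) return(u_coarse)
  pts <- grid_coordinates(fine_shape)
  for (ax in 1:3) pts[, ax] <- (pts[, ax] - (factor - 1) / 2) / factor
  out <- array(0, c(fine_shape, 3L))
  for (cc in 1:3) {
    out[, , , cc] <- factor * array(interpolate(u_coarse[, , , cc], pts), fine_shape)
  }
  out
}

# Scale a band width / smoothing std-dev to a coarser level: divide by the
# factor, floored at one voxel (but never raised above the unscaled value;
# zero stays zero).
scale_param <- function(x, factor) {
  if (x == 0) 0 else max(x / factor, min(x, 1))
}

#' Multi-resolution joint registration
#'
#' Runs [register_single_level()] on a coarse-to-fine pyramid (factors 4, 2,
#' 1 for three levels), warm-starting each level from the upsampled
#' displacement of the previous one. Band width and smoothing parameters are
#' divided by the level factor (floored at one voxel) so their physical
#' extent stays roughly constant.
#'
#' @inheritParams register_single_level
#' @return an `lsreg_registration` list as in [register_single_level()], with
#'   an additional `level_log` (list of per-level registration results
#'   without displacement fields) and `iterations` summed over levels.
#' @export
register_multilevel <- function(I_S, I_T, labels = NULL,
                                cfg = registration_config()) {
  s_arr <- as_field3d(I_S)
  t_arr <- as_field3d(I_T)
  check_same_grid(s_arr, t_arr, "source and target")
  factors <- rev(2^(seq_len(cfg$levels) - 1L))  # e.g. 4, 2, 1
  u <- NULL
  level_log <- list()
  total_iter <- 0L
  res <- NULL
  for (li in seq_along(factors)) {
    f <- factors[li]
    s_l <- downsample(s_arr, f)
    t_l <- downsample(t_arr, f)
    lab_l <- if (!is.null(labels)) downsample_labels(as_field3d(labels), f) else NULL
    cfg_l <- cfg
    cfg_l$gamma <- scale_param(cfg$gamma, f)
    cfg_l$sigma1 <- scale_param(cfg$sigma1, f)
    cfg_l$sigma2 <- scale_param(cfg$sigma2, f)
    cfg_l$sigma3 <- scale_param(cfg$sigma3, f)
    u0 <- if (is.null(u)) NULL else {
      upsample_displacement(u, factors[li - 1L] / f, dim(t_l))
    }
    res <- register_single_level(s_l, t_l, lab_l, cfg_l, u0)
    u <- res$u
    total_iter <- total_iter + res$iterations
    level_log[[li]] <- list(factor = f, iterations = res$iterations,
                            converged = res$converged, log = res$log)
  }
  structure(list(u = u, log = res$log, level_log = level_log,
                 iterations = total_iter, converged = res$converged,
                 dt_final = res$dt_final, config = cfg),
            class = "lsreg_registration")
}
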