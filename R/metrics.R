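# Evaluation measures: Dice overlap between binary regions and mean target
# registration error (TRE) in millimetres.

#' Dice overlap coefficient
#'
#' `2 |A ∩ B| / (|A| + |B|)` with volumes counted as voxel numbers. When a
#' label id is given, the comparison is between `labels == region`;
#' otherwise nonzero voxels are compared. Two empty regions have Dice
#' defined as 1 (flagged via attribute `both_empty`).
#'
#' @param A,B [label_map()]s or arrays on the same grid.
#' @param region optional region id; default compares all nonzero labels.
#' @return scalar in \[0, 1\].
#' @export
dice <- function(A, B, region = NULL) {
  a <- as_field3d(A)
  b <- as_field3d(B)
  check_same_grid(a, b, "label maps")
  ma <- if (is.null(region)) a > 0 else a == region
  mb <- if (is.null(region)) b > 0 else b == region
  na <- sum(ma)
  nb <- sum(mb)
  if (na + nb == 0L) {
    return(structure(1, both_empty = TRUE))
  }
  2 * sum(ma & mb) / (na + nb)
}

#' Target registration error (mm)
#'
#' Mean Euclidean distance between each source landmark `x_i` and its target
#' landmark pushed through the displacement, `y_i + u(y_i)`, with `u` sampled
#' at `y_i` by trilinear interpolation and each axis difference converted
#' from voxels to millimetres via the spacing before taking the norm.
#' `tre(landmarks, NULL)` gives the initial (pre-registration) error.
#'
#' @param landmarks a [landmark_set()] (paired target/source points, 0-based
#'   voxel coordinates, plus spacing).
#' @param u displacement field (4-D array, voxel units) or `NULL` for the
#'   zero field.
#' @param spacing optional spacing override (mm per voxel per axis).
#' @return mean TRE in millimetres.
#' @export
tre <- function(landmarks, u = NULL, spacing = NULL) {
  if (!inherits(landmarks, "landmark_set")) {
    stop("`landmarks` must be a landmark_set", call. = FALSE)
  }
  y <- landmarks$target
  x <- landmarks$source
  sp <- if (is.null(spacing)) landmarks$spacing else rep_len(as.numeric(spacing), 3L)
  moved <- y
  if (!is.null(u)) {
    for (cc in 1:3) moved[, cc] <- moved[, cc] + interpolate(u[, , , cc], y)
  }
  diff_mm <- sweep(x - moved, 2L, sp, `*`)
  mean(sqrt(rowSums(diff_mm^2)))
}
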