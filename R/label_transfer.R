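# Atlas label propagation: push the target's prior labels through the
# recovered displacement onto the source grid (forward splat), then close
# rasterization holes.

#' Propagate labels through a displacement field
#'
#' Forward-maps each labeled target voxel `y` to `y + u(y)` and splats its
#' label onto the nearest source voxel. When several source points land on
#' the same voxel, the label whose mapped point lies closest to the voxel
#' center wins. Rasterization holes inside the splatted region are then
#' closed by one pass of morphological closing (Euclidean radius 1), applied
#' per label and only over still-unlabeled voxels; the complement keeps
#' label 0. Collision and fill counts are recorded in attributes
#' `collisions` and `filled` of the result for auditability.
#'
#' @param labels_target prior [label_map()] (or integer array) on the target
#'   grid.
#' @param u displacement field (4-D array, voxel units) on the same grid.
#' @param close_holes apply the per-label closing pass (default TRUE); set
#'   FALSE to obtain the raw splatted set.
#' @return propagated labels, same type as `labels_target`, with attributes
#'   `collisions` (splat collisions) and `filled` (voxels filled by closing).
#' @export
propagate_labels <- function(labels_target, u, close_holes = TRUE) {
  lab <- as_field3d(labels_target)
  check_same_grid(lab, u, "labels and displacement")
  d <- dim(lab)
  out <- array(0L, d)
  idx <- which(lab > 0)
  collisions <- 0L
  filled <- 0L
  if (length(idx)) {
    # 0-based coordinates of labeled voxels
    i0 <- idx - 1L
    y <- cbind(i0 %% d[1L],
               (i0 %/% d[1L]) %% d[2L],
               i0 %/% (d[1L] * d[2L]))
    p <- y
    p[, 1L] <- p[, 1L] + u[, , , 1L][idx]
    p[, 2L] <- p[, 2L] + u[, , , 2L][idx]
    p[, 3L] <- p[, 3L] + u[, , , 3L][idx]
    r <- round(p)
    for (ax in 1:3) r[, ax] <- pmin(pmax(r[, ax], 0), d[ax] - 1L)
    dist2 <- rowSums((p - r)^2)
    tgt <- 1L + r[, 1L] + d[1L] * (r[, 2L] + d[2L] * r[, 3L])
    collisions <- sum(duplicated(tgt))
    # write farthest first so the closest source point wins each voxel
    ord <- order(dist2, decreasing = TRUE)
    out[tgt[ord]] <- lab[idx][ord]
    if (close_holes) {
      for (l in setdiff(sort(unique(as.vector(lab[idx]))), 0L)) {
        closed <- binary_close(out == l, 1)
        fill <- closed & out == 0L
        filled <- filled + sum(fill)
        out[fill] <- l
      }
    }
  }
  res <- if (inherits(labels_target, "label_map")) {
    label_map(out, labels_target$spacing)
  } else {
    out
  }
  attr(res, "collisions") <- collisions
  attr(res, "filled") <- filled
  res
}
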