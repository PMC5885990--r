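#' Scalar image volume on a regular grid
#'
#' Bundles a 3-D array of voxel intensities with the physical voxel spacing.
#' 2-D matrices are promoted to a single-slice 3-D volume. Axis order is
#' (x, y, z) matching R's array dimensions; coordinates are 0-based and
#' node-centered, so the continuous coordinate `p` falls exactly on node
#' index `p`.
#'
#' @param values numeric array (3-D) or matrix (2-D, promoted).
#' @param spacing physical size of one voxel per axis, in mm; strictly
#'   positive, recycled to length 3.
#' @return an object of class `image_volume` with fields `values` and
#'   `spacing`.
#' @examples
#' vol <- image_volume(array(runif(8 * 8 * 4), c(8, 8, 4)), spacing = c(1, 1, 2.5))
#' dim(vol)
#' @export
image_volume <- function(values, spacing = c(1, 1, 1)) {
  values <- as_field3d(values)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` components must be strictly positive", call. = FALSE)
  }
  structure(list(values = values, spacing = spacing), class = "image_volume")
}

#' Integer label map on a regular grid
#'
#' Region-membership field: 0 = background, k >= 1 = region k. Shares the
#' grid conventions of [image_volume()].
#'
#' @param labels integer array (3-D) or matrix; non-negative.
#' @param spacing voxel spacing in mm per axis.
#' @return an object of class `label_map` with fields `labels` and `spacing`.
#' @export
label_map <- function(labels, spacing = c(1, 1, 1)) {
  labels <- as_field3d(labels)
  if (any(labels < 0) || any(labels != round(labels))) {
    stop("labels must be non-negative integers", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = rep_len(as.numeric(spacing), 3L)),
            class = "label_map")
}

#' Paired landmark set
#'
#' Index-paired landmark coordinates in the target (`target`) and source
#' (`source`) image, in 0-based voxel units, plus the voxel spacing used to
#' convert voxel displacements to millimetres.
#'
#' @param target,source numeric matrices with one row per landmark and
#'   columns (x, y, z); must have the same number of rows.
#' @param spacing voxel spacing in mm per axis.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(target, source, spacing = c(1, 1, 1)) {
  target <- as_points(target)
  source <- as_points(source)
  if (nrow(target) != nrow(source)) {
    stop("target and source landmark lists must be index-paired (equal length)",
         call. = FALSE)
  }
  structure(list(target = target, source = source,
                 spacing = rep_len(as.numeric(spacing), 3L)),
            class = "landmark_set")
}

as_points <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) == 2L) p <- cbind(p, 0)
  if (ncol(p) != 3L) stop("points must have 2 or 3 columns", call. = FALSE)
  storage.mode(p) <- "double"
  colnames(p) <- c("x", "y", "z")
  p
}

# Coerce matrix / image_volume / label_map to a plain 3-D numeric array.
as_field3d <- function(x) {
  if (inherits(x, "image_volume")) x <- x$values
  if (inherits(x, "label_map")) x <- x$labels
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("expected a 2-D matrix or 3-D array", call. = FALSE)
  }
  x
}

# Spacing of a volume-like object, defaulting to unit voxels for bare arrays.
spacing_of <- function(x, default = c(1, 1, 1)) {
  if (inherits(x, c("image_volume", "label_map"))) x$spacing else default
}

# Zero vector field (Mx, My, Mz, 3) over the grid of `dim3`.
zero_displacement <- function(dim3) {
  array(0, c(dim3, 3L))
}

check_same_grid <- function(a, b, what = "fields") {
  if (!identical(dim(a)[1:3], dim(b)[1:3])) {
    stop(sprintf("%s are defined on different grids (%s vs %s)", what,
                 paste(dim(a)[1:3], collapse = "x"),
                 paste(dim(b)[1:3], collapse = "x")), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
dim.image_volume <- function(x) dim(x$values)

#' @export
dim.label_map <- function(x) dim(x$labels)

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  tb <- table(x$labels)
  cat(sprintf("<label_map> %s voxels, labels: %s\n",
              paste(dim(x$labels), collapse = "x"),
              paste(sprintf("%s (n=%d)", names(tb), as.integer(tb)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d paired landmarks, spacing %s mm\n",
              nrow(x$target), paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' Plot an axial slice of a volume
#'
#' Displays one z-slice of an image volume in grey scale, optionally with
#' label-map contours superimposed.
#'
#' @param x an [image_volume()] or 3-D array.
#' @param slice z-index of the slice (1-based); defaults to the middle slice.
#' @param labels optional [label_map()] whose region outlines are drawn.
#' @param ... further arguments passed to [graphics::image()].
#' @return invisibly, `x`.
#' @export
plot_slice <- function(x, slice = NULL, labels = NULL, ...) {
  v <- as_field3d(x)
  if (is.null(slice)) slice <- max(1L, dim(v)[3] %/% 2L)
  sl <- v[, , slice]
  graphics::image(seq_len(nrow(sl)), seq_len(ncol(sl)), sl,
                  col = grDevices::gray.colors(128, 0, 1), asp = 1,
                  xlab = "x", ylab = "y", useRaster = TRUE, ...)
  if (!is.null(labels)) {
    lv <- as_field3d(labels)[, , slice]
    for (k in setdiff(sort(unique(as.vector(lv))), 0)) {
      graphics::contour(seq_len(nrow(lv)), seq_len(ncol(lv)), (lv == k) + 0,
                        levels = 0.5, add = TRUE, drawlabels = FALSE, col = "red")
    }
  }
  invisible(x)
}

#' @export
plot.image_volume <- function(x, ...) plot_slice(x, ...)

#' @importFrom grDevices gray.colors
#' @importFrom graphics contour
NULL
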