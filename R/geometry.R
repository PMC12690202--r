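#' Construct a diagonal (scaling + translation) voxel-to-mm affine
#'
#' Builds the 4x4 affine mapping 0-based voxel indices to scanner millimetre
#' coordinates for an axis-aligned grid in RAS orientation.
#'
#' @param voxel_size Numeric length-3 vector of voxel edge lengths in mm.
#' @param origin mm coordinate of voxel (0, 0, 0). Defaults to placing the
#'   grid centre at the mm origin when `grid_shape` is supplied.
#' @param grid_shape Optional integer length-3 grid dimensions, used only to
#'   derive the centring origin.
#' @return A 4x4 numeric affine matrix.
#' @export
make_affine <- function(voxel_size, origin = NULL, grid_shape = NULL) {
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be positive and finite")
  if (is.null(origin)) {
    if (is.null(grid_shape)) {
      origin <- c(0, 0, 0)
    } else {
      origin <- -voxel_size * (as.numeric(grid_shape) - 1) / 2
    }
  }
  aff <- diag(4)
  diag(aff)[1:3] <- voxel_size
  aff[1:3, 4] <- origin
  aff
}

#' Rotation matrix from intrinsic z-y-x Euler angles
#'
#' @param yaw Rotation about the z axis, radians.
#' @param pitch Rotation about the y axis, radians.
#' @param roll Rotation about the x axis, radians.
#' @return A 3x3 rotation matrix (R = Rz(yaw) Ry(pitch) Rx(roll)).
#' @export
euler_rotation <- function(yaw = 0, pitch = 0, roll = 0) {
  cz <- cos(yaw); sz <- sin(yaw)
  cy <- cos(pitch); sy <- sin(pitch)
  cx <- cos(roll); sx <- sin(roll)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  rz %*% ry %*% rx
}

#' Specify a nucleus as a rotated ellipsoid
#'
#' Idealised nucleus geometry: an ellipsoid with the given semi-axis lengths,
#' rotated and translated into scanner mm space. The analysis depends only on
#' the mask having three distinct principal axes, not on anatomical shape.
#'
#' @param name Nucleus name, e.g. "SN", "putamen", "caudate".
#' @param hemisphere "L" or "R".
#' @param semi_axes Numeric length-3, ellipsoid semi-axis lengths in mm
#'   (in the ellipsoid's own frame, before rotation).
#' @param center mm coordinates of the ellipsoid centre.
#' @param rotation 3x3 rotation matrix applied to the ellipsoid frame.
#' @return An object of class `nucleus_shape`.
#' @export
nucleus_shape <- function(name, hemisphere, semi_axes, center,
                          rotation = diag(3)) {
  semi_axes <- as.numeric(semi_axes)
  center <- as.numeric(center)
  stopifnot(length(semi_axes) == 3L, length(center) == 3L)
  if (any(semi_axes <= 0)) stop("ellipsoid semi-axes must be positive")
  hemisphere <- match.arg(hemisphere, c("L", "R"))
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation must be a 3x3 orthonormal matrix")
  structure(list(name = name, hemisphere = hemisphere,
                 semi_axes = semi_axes, center = center, rotation = rotation),
            class = "nucleus_shape")
}

#' Rasterise an ellipsoid nucleus onto a voxel grid
#'
#' A voxel belongs to the mask when its mm centre lies inside the rotated
#' ellipsoid. Errors if the result is empty (nucleus outside the grid or
#' smaller than a voxel) or collides with previously placed labels.
#'
#' @param shape A [nucleus_shape()].
#' @param grid_shape Integer length-3 grid dimensions.
#' @param affine 4x4 voxel-to-mm affine.
#' @param label Integer label id for this nucleus.
#' @param existing Optional list of previously placed `roi_mask` objects the
#'   new mask must not overlap.
#' @return An object of class `roi_mask` with fields `label`, `name`,
#'   `hemisphere`, `indices` (0-based, lexicographic row order), `affine`,
#'   `n_voxels`.
#' @export
generate_nucleus_mask <- function(shape, grid_shape, affine, label = 1L,
                                  existing = NULL) {
  stopifnot(inherits(shape, "nucleus_shape"))
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))

  # bounding box of the rotated ellipsoid in mm: half-widths are the row
  # norms of R %*% diag(semi_axes)
  half <- sqrt(rowSums((shape$rotation %*% diag(shape$semi_axes))^2))
  lo_mm <- shape$center - half
  hi_mm <- shape$center + half
  inv <- solve(affine)
  corners <- as.matrix(expand.grid(c(lo_mm[1], hi_mm[1]),
                                   c(lo_mm[2], hi_mm[2]),
                                   c(lo_mm[3], hi_mm[3])))
  vox <- t(inv[1:3, 1:3] %*% t(corners) + inv[1:3, 4])
  lo <- pmax(floor(apply(vox, 2, min)), 0)
  hi <- pmin(ceiling(apply(vox, 2, max)), grid_shape - 1L)
  if (any(lo > hi))
    stop("degenerate geometry: nucleus '", shape$name, "' (", shape$hemisphere,
         ") lies outside the voxel grid")

  idx <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                               k = lo[3]:hi[3]))
  mm <- t(affine[1:3, 1:3] %*% t(idx) + affine[1:3, 4])
  local <- (mm - matrix(shape$center, nrow(mm), 3, byrow = TRUE)) %*%
    shape$rotation               # R^T (x - c), since x %*% R == t(t(R) %*% t(x))
  q <- (local[, 1] / shape$semi_axes[1])^2 +
       (local[, 2] / shape$semi_axes[2])^2 +
       (local[, 3] / shape$semi_axes[3])^2
  inside <- q <= 1
  if (!any(inside))
    stop("degenerate geometry: nucleus '", shape$name, "' (", shape$hemisphere,
         ") contains no voxel centre (sub-voxel or outside grid)")
  idx <- idx[inside, , drop = FALSE]
  ord <- order(idx[, 1], idx[, 2], idx[, 3])
  idx <- idx[ord, , drop = FALSE]
  dimnames(idx) <- NULL
  storage.mode(idx) <- "integer"

  if (length(existing)) {
    lin_new <- .linear_index(idx, grid_shape)
    for (m in existing) {
      if (any(lin_new %in% .linear_index(m$indices, grid_shape)))
        stop("placement error: nucleus '", shape$name, "' (",
             shape$hemisphere, ") overlaps label ", m$label,
             " ('", m$name, "' ", m$hemisphere, ")")
    }
  }

  structure(list(label = as.integer(label), name = shape$name,
                 hemisphere = shape$hemisphere, indices = idx,
                 affine = affine, n_voxels = nrow(idx)),
            class = "roi_mask")
}

# 1-based linear index into an array of dim grid_shape from 0-based triples
.linear_index <- function(idx, grid_shape) {
  1L + idx[, 1] + grid_shape[1] * (idx[, 2] + grid_shape[2] * idx[, 3])
}

#' Voxel centre coordinates in millimetres
#'
#' Applies the affine to the mask's 0-based voxel index triples. Row order is
#' stable (lexicographic by index).
#'
#' @param mask An `roi_mask`, or an m x 3 matrix of 0-based index triples.
#' @param affine 4x4 voxel-to-mm affine; defaults to the mask's own.
#' @return An m x 3 numeric matrix of mm coordinates.
#' @export
voxel_coordinates_mm <- function(mask, affine = NULL) {
  if (inherits(mask, "roi_mask")) {
    idx <- mask$indices
    if (is.null(affine)) affine <- mask$affine
  } else {
    idx <- as.matrix(mask)
    if (is.null(affine)) stop("affine required when mask is a bare index matrix")
  }
  stopifnot(ncol(idx) == 3L)
  if (abs(det(affine)) < .Machine$double.eps)
    stop("affine must be invertible")
  t(affine[1:3, 1:3] %*% t(idx) + affine[1:3, 4])
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("ROI mask: %s (%s), label %d, %d voxels\n",
              x$name, x$hemisphere, x$label, x$n_voxels))
  invisible(x)
}
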