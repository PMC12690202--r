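#' Principal orthogonal axes of an ROI by singular value decomposition
#'
#' Centres the voxel mm coordinates and takes the right singular vectors of
#' the centred coordinate matrix as the structure's three principal axes,
#' ordered by decreasing singular value. Coordinates should be in mm (via the
#' affine) so that anisotropic voxels do not bias the axes; pass index-space
#' coordinates explicitly to compare with implementations that use them.
#'
#' Before anatomical labeling the sign of each axis is fixed so that its
#' largest-magnitude component is positive, making the frame a deterministic
#' function of the coordinates.
#'
#' @param coords m x 3 matrix of point coordinates (mm), or an `roi_mask`.
#' @param min_points Minimum number of points required (default 4).
#' @return An object of class `axis_frame`: `centroid` (mm), `axes` (3x3,
#'   columns are unit axes, decreasing singular value), `singular_values`,
#'   `n_points`, `labels` (NULL until [label_axes_anatomically()]).
#' @export
compute_principal_axes <- function(coords, min_points = 4L) {
  if (inherits(coords, "roi_mask")) coords <- voxel_coordinates_mm(coords)
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L)
  m <- nrow(coords)
  if (m < min_points)
    stop("too few voxels for axis estimation: ", m, " < ", min_points)
  centroid <- colMeans(coords)
  x <- sweep(coords, 2, centroid)
  sv <- svd(x, nu = 0)
  d <- sv$d
  tol <- max(d) * 1e-8
  if (sum(d > tol) < 3L) {
    deficient <- which(d <= tol)
    stop("degenerate ROI geometry: coordinate cloud has rank ",
         sum(d > tol), "; deficient principal direction(s): ",
         paste(deficient, collapse = ", "))
  }
  axes <- sv$v
  # deterministic sign: largest-magnitude component of each axis positive
  for (j in 1:3) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  structure(list(centroid = centroid, axes = axes, singular_values = d,
                 n_points = m, labels = NULL, hemisphere = NA_character_,
                 label_tie = FALSE),
            class = "axis_frame")
}

# Cardinal target directions (RAS mm space) for each reporting label.
# The axis is oriented to point from the segment-1 end to the segment-n end:
# M -> L (hemisphere dependent), A -> P (-y), V -> D (+z).
.cardinal_directions <- function(hemisphere) {
  lateral <- if (hemisphere == "R") c(1, 0, 0) else c(-1, 0, 0)
  cbind("M-L" = lateral, "A-P" = c(0, -1, 0), "V-D" = c(0, 0, 1))
}

#' Assign anatomical labels (M-L, A-P, V-D) to principal axes
#'
#' Each principal axis is matched to the anatomical cardinal direction with
#' which its absolute cosine is largest, resolved globally as the assignment
#' of axes to the three labels that maximises the total absolute cosine over
#' all six permutations (so two axes can never claim the same direction).
#' Signs are then flipped so the labeled axes point medial-to-lateral,
#' anterior-to-posterior and ventral-to-dorsal: segment 1 is always the
#' M/A/V end and segment n the L/P/D end. Exact ties between permutations are
#' broken toward singular-value order and flagged in `label_tie`.
#'
#' @param frame An `axis_frame` from [compute_principal_axes()].
#' @param hemisphere "L" or "R"; determines which x direction is lateral.
#' @return The frame with `labels` (per axis column), reoriented `axes`, and
#'   `label_tie`.
#' @export
label_axes_anatomically <- function(frame, hemisphere = c("R", "L")) {
  stopifnot(inherits(frame, "axis_frame"))
  hemisphere <- match.arg(hemisphere)
  dirs <- .cardinal_directions(hemisphere)
  cosm <- abs(crossprod(frame$axes, dirs))   # 3 axes x 3 labels

  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  tot <- vapply(perms, function(p) sum(cosm[cbind(1:3, p)]), numeric(1))
  best <- max(tot)
  cand <- which(tot >= best - 1e-12)
  # tie-break toward identity (singular-value order maps straight onto the
  # label order M-L, A-P, V-D); perms are listed with identity first
  pick <- cand[1]
  frame$label_tie <- length(cand) > 1L

  p <- perms[[pick]]
  labels <- colnames(dirs)[p]
  axes <- frame$axes
  for (a in 1:3) {
    d <- dirs[, p[a]]
    if (sum(axes[, a] * d) < 0) axes[, a] <- -axes[, a]
  }
  frame$axes <- axes
  frame$labels <- labels
  frame$hemisphere <- hemisphere
  frame
}

#' Partition an ROI into equidistant segments along a labeled axis
#'
#' Projects every voxel centre onto the requested axis; two bounding
#' hyperplanes orthogonal to the axis pass through the outermost projections,
#' and n-1 equally spaced parallel hyperplanes subdivide the interval into n
#' equidistant segments. A voxel with projection p falls in segment
#' `floor(n * (p - pmin) / (pmax - pmin)) + 1`, with p = pmax closed into
#' segment n, so the segments partition the mask.
#'
#' @param coords m x 3 mm coordinate matrix, or an `roi_mask`.
#' @param frame A labeled `axis_frame` for the same coordinates.
#' @param axis_label One of "M-L", "A-P", "V-D".
#' @param n Number of segments (default 7).
#' @return Object of class `segment_assignment`: integer `segment` (1..n) per
#'   voxel, `n`, `axis_label`, `boundaries` (n+1 increasing projections, mm).
#' @export
segment_along_axis <- function(coords, frame, axis_label, n = 7L) {
  if (inherits(coords, "roi_mask")) coords <- voxel_coordinates_mm(coords)
  coords <- as.matrix(coords)
  stopifnot(inherits(frame, "axis_frame"))
  if (is.null(frame$labels))
    stop("frame has no anatomical labels; call label_axes_anatomically() first")
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("number of segments must be at least 2")
  a <- match(axis_label, frame$labels)
  if (is.na(a)) stop("unknown axis label '", axis_label, "'")

  p <- as.numeric(sweep(coords, 2, frame$centroid) %*% frame$axes[, a])
  pmin <- min(p); pmax <- max(p)
  extent <- pmax - pmin
  if (extent <= 0)
    stop("degenerate projection: all voxels project to one point on the ",
         axis_label, " axis")
  seg <- pmin(floor(n * (p - pmin) / extent) + 1L, n)
  structure(list(segment = as.integer(seg), n = n, axis_label = axis_label,
                 boundaries = pmin + (0:n) * extent / n),
            class = "segment_assignment")
}

#' @export
print.axis_frame <- function(x, ...) {
  cat("Principal axis frame (", x$n_points, " points)\n", sep = "")
  cat("  centroid (mm): ", paste(sprintf("%.2f", x$centroid), collapse = ", "),
      "\n", sep = "")
  cat("  singular values: ",
      paste(sprintf("%.2f", x$singular_values), collapse = ", "), "\n",
      sep = "")
  if (!is.null(x$labels)) {
    for (a in 1:3)
      cat(sprintf("  %s axis: [%s]\n", x$labels[a],
                  paste(sprintf("% .3f", x$axes[, a]), collapse = ", ")))
    if (isTRUE(x$label_tie)) cat("  note: label assignment tie-broken\n")
  } else {
    cat("  (axes unlabeled; call label_axes_anatomically())\n")
  }
  invisible(x)
}
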