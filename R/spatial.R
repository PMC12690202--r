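#' Per-segment median susceptibility functions for one subject and ROI
#'
#' For each of the three labeled principal axes, computes the median
#' susceptibility within each of the n equidistant segments (conventional
#' median: even counts average the central pair), together with segment voxel
#' counts and the overall ROI mean. Empty interior segments (possible for
#' sparse masks) yield missing medians and are carried as NA downstream.
#'
#' @param volume 3D numeric array on the mask's grid.
#' @param mask An `roi_mask`.
#' @param frame Labeled `axis_frame` computed from this mask.
#' @param n Number of segments per axis (default 7).
#' @param min_voxels Minimum mask size accepted; default `3 * n`, below which
#'   per-segment medians are not meaningful.
#' @return Object of class `spatial_function`: `medians` and `counts`
#'   (3 x n matrices, rows named by axis label), `roi_mean`, `n`,
#'   `roi`, `hemisphere`, and `subject` (filled by the pipeline).
#' @export
compute_spatial_function <- function(volume, mask, frame, n = 7L,
                                     min_voxels = 3L * n) {
  stopifnot(inherits(mask, "roi_mask"), inherits(frame, "axis_frame"))
  n <- as.integer(n)
  grid_shape <- dim(volume)
  if (length(grid_shape) != 3L)
    stop("volume must be a 3D array")
  if (any(mask$indices < 0L) ||
      any(sweep(mask$indices, 2, grid_shape, ">=")))
    stop("grid mismatch: mask indices fall outside the volume dimensions")
  if (frame$n_points != mask$n_voxels)
    stop("frame/mask mismatch: frame built from ", frame$n_points,
         " voxels, mask has ", mask$n_voxels)
  if (is.null(frame$labels))
    stop("frame has no anatomical labels; call label_axes_anatomically() first")
  if (mask$n_voxels < min_voxels)
    stop("mask too small for ", n, "-segment analysis: ", mask$n_voxels,
         " voxels < ", min_voxels)

  vals <- volume[.linear_index(mask$indices, grid_shape)]
  coords <- voxel_coordinates_mm(mask)
  medians <- matrix(NA_real_, 3, n, dimnames = list(frame$labels, NULL))
  counts <- matrix(0L, 3, n, dimnames = list(frame$labels, NULL))
  for (lab in frame$labels) {
    seg <- segment_along_axis(coords, frame, lab, n)$segment
    for (s in seq_len(n)) {
      in_s <- seg == s
      counts[lab, s] <- sum(in_s)
      if (counts[lab, s] > 0L) medians[lab, s] <- stats::median(vals[in_s])
    }
  }
  structure(list(medians = medians, counts = counts,
                 roi_mean = mean(vals), n = n,
                 roi = mask$name, hemisphere = mask$hemisphere,
                 subject = NA_character_),
            class = "spatial_function")
}

#' Group-averaged spatial functions
#'
#' Segment-wise across-subject mean and SD of per-subject spatial functions,
#' using available cases per segment (subjects whose segment median is
#' missing are dropped for that segment only). SD is reported only where at
#' least two subjects contribute.
#'
#' @param functions List of `spatial_function` objects sharing ROI and n.
#' @param groups Character/factor vector of group labels, one per function.
#' @return Named list (one per group level) of `group_spatial_function`
#'   objects: `group`, `mean`, `sd`, `count` (3 x n matrices), `n`, `roi`.
#' @export
group_average_function <- function(functions, groups) {
  stopifnot(length(functions) == length(groups), length(functions) > 0)
  n <- functions[[1]]$n
  roi <- functions[[1]]$roi
  labs <- rownames(functions[[1]]$medians)
  for (f in functions)
    if (f$n != n || !identical(rownames(f$medians), labs))
      stop("all spatial functions must share n and axis labels")
  groups <- as.factor(groups)
  out <- list()
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (!length(idx)) stop("empty group: ", g)
    arr <- vapply(functions[idx], function(f) f$medians,
                  matrix(0, 3, n))                     # 3 x n x m
    mn <- apply(arr, c(1, 2), function(v) mean(v, na.rm = TRUE))
    cnt <- apply(arr, c(1, 2), function(v) sum(!is.na(v)))
    sdv <- apply(arr, c(1, 2), function(v) {
      v <- v[!is.na(v)]
      if (length(v) >= 2) stats::sd(v) else NA_real_
    })
    mn[cnt == 0] <- NA_real_
    dimnames(mn) <- dimnames(cnt) <- dimnames(sdv) <- list(labs, NULL)
    out[[g]] <- structure(list(group = g, mean = mn, sd = sdv,
                               count = cnt, n = n, roi = roi),
                          class = "group_spatial_function")
  }
  out
}

#' Segment index of the maximum of a spatial function
#'
#' Returns the 1-based index of the largest entry along one axis; exact ties
#' are broken toward the lowest index and flagged via the `"tie"` attribute.
#'
#' @param x A `spatial_function`, `group_spatial_function`, or numeric vector.
#' @param axis Axis label, required unless `x` is a bare vector.
#' @return Integer segment index with logical attribute `tie`.
#' @export
peak_segment <- function(x, axis = NULL) {
  v <- if (is.numeric(x)) {
    x
  } else if (inherits(x, "spatial_function")) {
    x$medians[axis, ]
  } else if (inherits(x, "group_spatial_function")) {
    x$mean[axis, ]
  } else stop("unsupported input")
  if (all(is.na(v))) stop("all segment values missing; no peak defined")
  top <- max(v, na.rm = TRUE)
  hits <- which(v == top)
  structure(as.integer(hits[1]), tie = length(hits) > 1L)
}

#' Peak trajectory across ordered disease stages
#'
#' Tracks the peak segment of group-averaged functions ordered by stage and
#' labels each step anatomically: on the M-L axis a move toward segment 1 is
#' a "medial shift" and toward segment n a "lateral shift" (anterior /
#' posterior on A-P, ventral / dorsal on V-D), since segment 1 is always the
#' M/A/V end of the labeled axis.
#'
#' @param group_functions List of `group_spatial_function` in stage order.
#' @param axis Axis label.
#' @param stages Optional stage names; defaults to the group labels.
#' @return Object of class `peak_trajectory`: data frame `peaks` (stage,
#'   peak, tie) and character `shifts` (length one less than stages).
#' @export
peak_trajectory <- function(group_functions, axis, stages = NULL) {
  stopifnot(length(group_functions) >= 2)
  labs_ok <- vapply(group_functions,
                    function(g) axis %in% rownames(g$mean), logical(1))
  if (!all(labs_ok))
    stop("inconsistent axis labels across group functions")
  if (is.null(stages))
    stages <- vapply(group_functions, function(g) g$group, character(1))
  pk <- lapply(group_functions, peak_segment, axis = axis)
  peaks <- vapply(pk, as.integer, integer(1))
  ties <- vapply(pk, function(p) attr(p, "tie"), logical(1))

  toward1 <- c("M-L" = "medial shift", "A-P" = "anterior shift",
               "V-D" = "ventral shift")
  towardn <- c("M-L" = "lateral shift", "A-P" = "posterior shift",
               "V-D" = "dorsal shift")
  shifts <- character(length(peaks) - 1L)
  for (i in seq_along(shifts)) {
    d <- peaks[i + 1L] - peaks[i]
    shifts[i] <- if (d == 0) "unchanged"
                 else if (d > 0) towardn[[axis]] else toward1[[axis]]
  }
  structure(list(peaks = data.frame(stage = stages, peak = peaks, tie = ties,
                                    stringsAsFactors = FALSE),
                 shifts = shifts, axis = axis),
            class = "peak_trajectory")
}

#' @export
print.spatial_function <- function(x, ...) {
  cat(sprintf("Spatial function: %s (%s), n = %d, ROI mean = %.3f\n",
              x$roi, x$hemisphere, x$n, x$roi_mean))
  print(round(x$medians, 3))
  invisible(x)
}

#' @export
print.peak_trajectory <- function(x, ...) {
  cat("Peak trajectory on the", x$axis, "axis\n")
  print(x$peaks, row.names = FALSE)
  cat("  shifts:", paste(x$shifts, collapse = " -> "), "\n")
  invisible(x)
}

#' Plot group-averaged spatial functions
#'
#' One panel per axis, one line per group, mean per-segment susceptibility
#' against segment index.
#'
#' @param x A list of `group_spatial_function` objects (as returned by
#'   [group_average_function()]) or a single one.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot_group_functions <- function(x, ...) {
  if (inherits(x, "group_spatial_function")) x <- list(x)
  labs <- rownames(x[[1]]$mean)
  old <- graphics::par(mfrow = c(1, length(labs)))
  on.exit(graphics::par(old))
  for (lab in labs) {
    m <- vapply(x, function(g) g$mean[lab, ], numeric(x[[1]]$n))
    graphics::matplot(seq_len(nrow(m)), m, type = "b", pch = 16, lty = 1,
                      xlab = paste(lab, "segment"),
                      ylab = "median susceptibility", ...)
    graphics::legend("topleft", legend = vapply(x, `[[`, "", "group"),
                     col = seq_along(x), lty = 1, pch = 16, bty = "n",
                     cex = 0.8)
  }
  invisible(x)
}
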