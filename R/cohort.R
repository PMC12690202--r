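#' Default nucleus geometry (idealised rotated ellipsoids)
#'
#' Bilateral substantia nigra, putamen and caudate as mirrored rotated
#' ellipsoids in scanner mm space (grid-centred RAS frame). Geometry is
#' idealised: the analysis only requires distinct principal axes, not
#' anatomical shape.
#'
#' @return Named list of [nucleus_shape()] objects (`SN_L`, `SN_R`, ...).
#' @export
default_nuclei <- function() {
  # mild obliquity everywhere so no principal axis is locked to the slice
  # direction (nuclei sit obliquely in the scanner frame; an exactly
  # slice-aligned thin axis would sample only a few discrete planes)
  spec <- list(
    SN      = list(semi = c(8, 4, 3), center = c(10, -6, -12),
                   rot = euler_rotation(0.35, 0.25, 0.2)),
    putamen = list(semi = c(6.5, 14, 7), center = c(17, 0, -2),
                   rot = euler_rotation(-0.25, 0.1, 0.15)),
    caudate = list(semi = c(5, 10, 5.5), center = c(9, 13, 9),
                   rot = euler_rotation(-0.15, 0.12, 0.1))
  )
  mx <- diag(c(-1, 1, 1))
  out <- list()
  for (nm in names(spec)) {
    s <- spec[[nm]]
    out[[paste0(nm, "_R")]] <- nucleus_shape(nm, "R", s$semi, s$center, s$rot)
    out[[paste0(nm, "_L")]] <- nucleus_shape(nm, "L", s$semi,
                                             s$center * c(-1, 1, 1),
                                             mx %*% s$rot %*% mx)
  }
  out
}

#' Default baseline susceptibilities (healthy-control regional means)
#'
#' Mean regional susceptibility (arbitrary, ppb-like units) per nucleus for
#' the more-affected/dominant and less-affected/non-dominant hemisphere,
#' matching typical healthy-control deep-gray values.
#'
#' @return 3 x 2 matrix, rows SN/putamen/caudate, columns MAS/LAS.
#' @export
default_baselines <- function() {
  matrix(c(95.63, 87.81, 39.17, 34.88, 28.06, 27.09), 3, 2, byrow = TRUE,
         dimnames = list(c("SN", "putamen", "caudate"), c("MAS", "LAS")))
}

#' Default within-nucleus gradient specifications
#'
#' One smooth unimodal (Gaussian-bump) susceptibility gradient per nucleus
#' along a designated principal axis, peaking at a configurable segment.
#' `peak_by_stage` optionally moves the peak with disease stage (named
#' early/middle/late); unnamed stages and controls use `peak`. The bump is
#' centred to zero mean over the ROI so the configured baseline remains the
#' exact ROI mean. Defaults place iron laterally in the SN, posteriorly in
#' the putamen and anteriorly in the caudate.
#'
#' @return Named list per nucleus: `axis`, `peak`, `amplitude`,
#'   `width_segments`, `peak_by_stage`.
#' @export
default_gradients <- function() {
  list(
    SN      = list(axis = "M-L", peak = 7, amplitude = 30,
                   width_segments = 1.2, peak_by_stage = NULL),
    putamen = list(axis = "A-P", peak = 6, amplitude = 20,
                   width_segments = 1.2, peak_by_stage = NULL),
    caudate = list(axis = "A-P", peak = 2, amplitude = 15,
                   width_segments = 1.2, peak_by_stage = NULL)
  )
}

#' Default iron-to-clinical couplings
#'
#' Each entry draws one clinical score as a linear function of a lateralized
#' regional iron level plus noise, calibrated so the within-group population
#' correlation equals `r`.
#'
#' @return List of coupling specs: `score`, `nucleus`, `hemisphere`
#'   ("MAS"/"LAS"), `r`, `group`.
#' @export
default_coupling <- function() {
  list(
    list(score = "updrs3_total", nucleus = "SN", hemisphere = "MAS",
         r = 0.35, group = "PIGD"),
    list(score = "pigd_score", nucleus = "caudate", hemisphere = "MAS",
         r = -0.271, group = "PIGD"),
    list(score = "hy", nucleus = "putamen", hemisphere = "LAS",
         r = -0.311, group = "TD")
  )
}

#' Synthetic cohort configuration
#'
#' Bundles every knob of the generator: design sizes, grid geometry, nucleus
#' shapes, baseline susceptibilities, within-nucleus gradients, subtype-
#' specific stage offsets (the inverted-U and S-shaped temporal presets),
#' noise levels and clinical couplings. Defaults emulate a three-group
#' Parkinson QSM study design (47 HC, 55 PIGD, 53 TD; stages 11/28/16 and
#' 12/26/15).
#'
#' @param group_sizes Named counts for HC, PIGD, TD.
#' @param stage_sizes Named list per subtype of early/middle/late counts
#'   summing to the subtype size.
#' @param grid_shape,voxel_size Voxel grid dimensions and edge lengths (mm);
#'   the default voxel is anisotropic (0.9 x 0.9 x 2 mm).
#' @param nuclei List of [nucleus_shape()] (see [default_nuclei()]).
#' @param baselines 3 x 2 baseline matrix (see [default_baselines()]).
#' @param gradients Gradient specs (see [default_gradients()]).
#' @param stage_offsets Named list per subtype of additive early/middle/late
#'   offsets; the PIGD default rises then falls (inverted U), the TD default
#'   rises, falls, rises (S-shape).
#' @param subject_sd Between-subject SD per nucleus.
#' @param noise_sd Voxel-level Gaussian noise SD.
#' @param coupling Clinical couplings (see [default_coupling()]).
#' @param n_segments Segments per axis (default 7).
#' @param seed Default RNG seed for [generate_cohort()].
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(HC = 47, PIGD = 55, TD = 53),
                          stage_sizes = list(
                            PIGD = c(early = 11, middle = 28, late = 16),
                            TD = c(early = 12, middle = 26, late = 15)),
                          grid_shape = c(64, 64, 24),
                          voxel_size = c(0.9, 0.9, 2),
                          nuclei = default_nuclei(),
                          baselines = default_baselines(),
                          gradients = default_gradients(),
                          stage_offsets = list(
                            PIGD = c(early = 25, middle = 25, late = -25),
                            TD = c(early = 25, middle = -25, late = 25)),
                          subject_sd = c(SN = 33, putamen = 20, caudate = 14),
                          noise_sd = 10,
                          coupling = default_coupling(),
                          n_segments = 7L,
                          seed = 1L) {
  cfg <- structure(list(group_sizes = group_sizes, stage_sizes = stage_sizes,
                        grid_shape = as.integer(grid_shape),
                        voxel_size = as.numeric(voxel_size),
                        nuclei = nuclei, baselines = baselines,
                        gradients = gradients, stage_offsets = stage_offsets,
                        subject_sd = subject_sd, noise_sd = noise_sd,
                        coupling = coupling,
                        n_segments = as.integer(n_segments),
                        seed = as.integer(seed)),
                   class = "cohort_config")
  .validate_config(cfg)
  cfg
}

.validate_config <- function(cfg) {
  if (any(cfg$group_sizes < 0)) stop("group sizes must be non-negative")
  for (g in names(cfg$stage_sizes)) {
    if (any(cfg$stage_sizes[[g]] < 0)) stop("stage sizes must be non-negative")
    if (sum(cfg$stage_sizes[[g]]) != cfg$group_sizes[[g]])
      stop("stage sizes for ", g, " must sum to the ", g, " group size")
  }
  if (any(cfg$voxel_size <= 0)) stop("voxel_size must be positive")
  if (cfg$n_segments < 2L) stop("n_segments must be at least 2")
  for (nm in names(cfg$gradients)) {
    gr <- cfg$gradients[[nm]]
    if (!gr$axis %in% c("M-L", "A-P", "V-D"))
      stop("unknown gradient axis label '", gr$axis, "' for ", nm)
    if (gr$amplitude < 0) stop("gradient amplitude must be non-negative")
    pk <- c(gr$peak, gr$peak_by_stage)
    if (any(pk < 1 | pk > cfg$n_segments))
      stop("gradient peak segment for ", nm, " must lie in 1..",
           cfg$n_segments)
  }
  for (cp in cfg$coupling) {
    if (!is.finite(cp$r) || abs(cp$r) >= 1)
      stop("coupling correlation must lie strictly inside (-1, 1)")
  }
  invisible(cfg)
}

#' Stage-varying gradient-peak presets
#'
#' Returns a config whose SN medial-lateral gradient peak moves with disease
#' stage: the PIGD preset runs segments 4 -> 7 -> 4 (lateral then medial
#' shift) and the TD preset 7 -> 4 -> 7 (medial then lateral shift) from
#' early to late stage.
#'
#' @param config A [cohort_config()].
#' @param subtype "PIGD" or "TD".
#' @return The modified config.
#' @export
preset_sn_ml_trajectory <- function(config, subtype = c("PIGD", "TD")) {
  subtype <- match.arg(subtype)
  config$gradients$SN$peak_by_stage <-
    if (subtype == "PIGD") c(early = 4, middle = 7, late = 4)
    else c(early = 7, middle = 4, late = 7)
  .validate_config(config)
  config
}

.contralateral <- function(side) ifelse(side == "R", "L", "R")

# Build masks and labeled frames once per config. Labels 1..6 in the fixed
# order SN_L, SN_R, putamen_L, putamen_R, caudate_L, caudate_R.
.build_geometry <- function(cfg) {
  affine <- make_affine(cfg$voxel_size, grid_shape = cfg$grid_shape)
  order_names <- c("SN_L", "SN_R", "putamen_L", "putamen_R",
                   "caudate_L", "caudate_R")
  order_names <- order_names[order_names %in% names(cfg$nuclei)]
  if (!length(order_names)) order_names <- names(cfg$nuclei)
  masks <- list()
  for (i in seq_along(order_names)) {
    nm <- order_names[i]
    masks[[nm]] <- generate_nucleus_mask(cfg$nuclei[[nm]], cfg$grid_shape,
                                         affine, label = i,
                                         existing = masks)
  }
  frames <- lapply(masks, function(m)
    label_axes_anatomically(compute_principal_axes(m), m$hemisphere))
  # normalised axial position (0..1) of every mask voxel along its gradient
  # axis, reused for every subject's gradient bump
  grad_pos <- list()
  for (nm in names(masks)) {
    gr <- cfg$gradients[[masks[[nm]]$name]]
    if (is.null(gr)) { grad_pos[[nm]] <- NULL; next }
    seg <- segment_along_axis(masks[[nm]], frames[[nm]], gr$axis,
                              cfg$n_segments)
    p <- seg$boundaries
    coords <- voxel_coordinates_mm(masks[[nm]])
    a <- match(gr$axis, frames[[nm]]$labels)
    proj <- as.numeric(sweep(coords, 2, frames[[nm]]$centroid) %*%
                         frames[[nm]]$axes[, a])
    grad_pos[[nm]] <- (proj - p[1]) / (p[length(p)] - p[1])
  }
  list(affine = affine, masks = masks, frames = frames, grad_pos = grad_pos)
}

# centred Gaussian bump values over a mask for a given peak segment
.gradient_bump <- function(pos, peak, amplitude, width_segments, n) {
  s_peak <- (peak - 0.5) / n
  sigma <- width_segments / n
  b <- amplitude * exp(-(pos - s_peak)^2 / (2 * sigma^2))
  b - mean(b)
}

.resolve_peak <- function(gr, stage) {
  if (!is.null(gr$peak_by_stage) && !is.na(stage) &&
      stage %in% names(gr$peak_by_stage))
    return(gr$peak_by_stage[[stage]])
  gr$peak
}

#' Generate one subject's susceptibility volume
#'
#' Voxel value = nucleus level (baseline + stage offset + subject random
#' effect, supplied via `levels`) + a centred Gaussian gradient bump along
#' the nucleus's designated axis + Gaussian voxel noise; background voxels
#' are zero plus noise.
#'
#' @param geometry Output of the internal geometry builder; obtained via
#'   [cohort_geometry()].
#' @param config A [cohort_config()].
#' @param levels Named numeric: constant susceptibility level per mask
#'   (names matching `geometry$masks`).
#' @param stage Disease stage ("early"/"middle"/"late") or NA; selects
#'   stage-dependent gradient peaks when configured.
#' @param seed Optional seed (set only if non-NULL, so the cohort generator
#'   can run the op inside one RNG stream).
#' @return 3D numeric array.
#' @export
generate_qsm_volume <- function(geometry, config, levels,
                                stage = NA_character_, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vol <- array(if (config$noise_sd > 0)
                 stats::rnorm(prod(config$grid_shape), 0, config$noise_sd)
               else 0,
               dim = config$grid_shape)
  for (nm in names(geometry$masks)) {
    m <- geometry$masks[[nm]]
    lin <- .linear_index(m$indices, config$grid_shape)
    val <- levels[[nm]]
    gr <- config$gradients[[m$name]]
    if (!is.null(gr) && gr$amplitude > 0) {
      val <- val + .gradient_bump(geometry$grad_pos[[nm]],
                                  .resolve_peak(gr, stage),
                                  gr$amplitude, gr$width_segments,
                                  config$n_segments)
    }
    vol[lin] <- vol[lin] + val
  }
  vol
}

#' Masks, frames and label volume for a configuration
#'
#' Deterministic (no RNG): rasterises every nucleus, computes labeled
#' principal-axis frames and the shared integer label volume.
#'
#' @param config A [cohort_config()].
#' @return List: `affine`, `masks`, `frames`, `label_array`, `label_map`
#'   (data frame label/nucleus/hemisphere), `grad_pos`.
#' @export
cohort_geometry <- function(config) {
  g <- .build_geometry(config)
  lab <- array(0L, config$grid_shape)
  for (m in g$masks)
    lab[.linear_index(m$indices, config$grid_shape)] <- m$label
  g$label_array <- lab
  g$label_map <- data.frame(
    label = vapply(g$masks, `[[`, integer(1), "label"),
    nucleus = vapply(g$masks, `[[`, character(1), "name"),
    hemisphere = vapply(g$masks, `[[`, character(1), "hemisphere"),
    stringsAsFactors = FALSE, row.names = NULL)
  g
}

# distribute an integer total over k items with per-item maximum, using the
# current RNG stream; deterministic given the stream state
.distribute_items <- function(total, k, max_item = 4L) {
  total <- min(total, k * max_item)
  items <- integer(k)
  if (total > 0) {
    raw <- as.integer(stats::rmultinom(1, total, rep(1, k)))
    overflow <- sum(pmax(raw - max_item, 0L))
    items <- pmin(raw, max_item)
    while (overflow > 0L) {
      room <- which(items < max_item)
      take <- room[seq_len(min(length(room), overflow))]
      items[take] <- items[take] + 1L
      overflow <- overflow - length(take)
    }
  }
  items
}

# draw tremor/PIGD item totals reproducing the configured subtype under the
# ratio rule, with a cap-aware deterministic fix-up loop (item scores are
# bounded at 4, so totals are capped at 4 * item count)
.draw_items <- function(subtype, pigd_total, rule = subtype_rule(),
                        max_item = 4L) {
  tre_cap <- rule$n_tremor * max_item
  pig_cap <- rule$n_pigd * max_item
  ratio_target <- switch(subtype,
    PIGD = stats::runif(1, 0.25, 0.85),
    TD = stats::runif(1, 1.25, 3.0),
    intermediate = stats::runif(1, 0.95, 1.10))
  pigd_total <- min(pigd_total, pig_cap)
  if (subtype != "TD") pigd_total <- max(pigd_total, 1L)
  tremor_total <- as.integer(min(round(ratio_target *
                                         (pigd_total / rule$n_pigd) *
                                         rule$n_tremor), tre_cap))
  if (subtype == "TD" && pigd_total == 0L) tremor_total <- max(tremor_total, 1L)
  ratio_of <- function(tt, tp) {
    mt <- tt / rule$n_tremor; mp <- tp / rule$n_pigd
    if (mp == 0) Inf else mt / mp
  }
  in_class <- function(r) switch(subtype,
    TD = r >= rule$td_threshold,
    PIGD = r <= rule$pigd_threshold && r >= 0,
    intermediate = r > rule$pigd_threshold && r < rule$td_threshold)
  for (iter in 1:400) {
    r <- ratio_of(tremor_total, pigd_total)
    if (in_class(r) && (tremor_total > 0 || pigd_total > 0)) break
    need_higher <- switch(subtype,
      TD = TRUE,                                  # need r >= 1.15
      PIGD = FALSE,                               # need r <= 0.9
      intermediate = r <= rule$pigd_threshold)    # move into (0.9, 1.15)
    if (need_higher) {
      if (tremor_total < tre_cap) tremor_total <- tremor_total + 1L
      else pigd_total <- max(pigd_total - 1L,
                             if (subtype == "TD") 0L else 1L)
    } else {
      if (tremor_total > 0L) tremor_total <- tremor_total - 1L
      else pigd_total <- min(pigd_total + 1L, pig_cap)
    }
  }
  stopifnot(in_class(ratio_of(tremor_total, pigd_total)))
  tremor <- .distribute_items(tremor_total, rule$n_tremor, max_item)
  pigd <- .distribute_items(pigd_total, rule$n_pigd, max_item)
  list(tremor = tremor, pigd = pigd)
}

.round_clip <- function(x, lo, hi, step = 1) {
  pmin(pmax(round(x / step) * step, lo), hi)
}

#' Generate clinical scores for a subject table
#'
#' Draws demographics-conditional clinical scores; scores named in the
#' coupling specs are generated as `r * z_iron + sqrt(1 - r^2) * noise` on a
#' standardised scale (z-scoring the lateralized regional iron level within
#' the coupled group), so the within-group population correlation equals the
#' configured `r` before rounding and range clipping. Tremor and PIGD item
#' scores are drawn so that the ratio rule reproduces each subject's
#' configured subtype exactly.
#'
#' @param subjects Data frame with at least `group`, `subtype`, `stage`,
#'   `onset_side` columns.
#' @param iron_levels n x mask matrix of subject-level regional iron
#'   (columns named like `SN_L`).
#' @param config A [cohort_config()].
#' @param seed Optional seed (NULL to use the current RNG stream).
#' @return The subject data frame with score columns appended.
#' @export
generate_clinical_scores <- function(subjects, iron_levels, config,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(subjects)
  is_pd <- subjects$group == "PD"

  subjects$age <- round(stats::rnorm(n, 65, 7), 1)
  sex_p <- ifelse(!is_pd, 0.36, ifelse(subjects$subtype == "PIGD", 0.47, 0.58))
  subjects$sex <- ifelse(stats::runif(n) < sex_p, "M", "F")
  subjects$education <- .round_clip(stats::rnorm(n, 9.5, 2), 0, 20)

  ledd <- numeric(n)
  pigd_i <- which(is_pd & subjects$subtype == "PIGD")
  td_i <- which(is_pd & subjects$subtype == "TD")
  ledd[pigd_i] <- 25 * round(stats::rlnorm(length(pigd_i),
                                           log(400), 0.9) / 25)
  td_zero <- stats::runif(length(td_i)) < 0.25
  ledd[td_i] <- ifelse(td_zero, 0,
                       25 * round(stats::rlnorm(length(td_i),
                                                log(300), 0.9) / 25))
  subjects$ledd <- ledd

  subjects$moca <- .round_clip(stats::rnorm(n, ifelse(is_pd, 23, 25.5),
                                            ifelse(is_pd, 3, 2)), 0, 30)
  subjects$mmse <- .round_clip(stats::rnorm(n, ifelse(is_pd, 26.5, 28),
                                            ifelse(is_pd, 2.5, 1.5)), 0, 30)
  subjects$hama <- ifelse(is_pd, .round_clip(stats::rnorm(n, 11, 5), 0, 56),
                          NA_real_)
  subjects$hamd <- ifelse(is_pd, .round_clip(stats::rnorm(n, 11, 5), 0, 52),
                          NA_real_)

  # latent standard-normal drivers per coupled score, correlated with the
  # designated lateralized iron level within the coupled group
  latent <- list(
    updrs3_total = stats::rnorm(n),
    pigd_score = stats::rnorm(n),
    hy = stats::rnorm(n)
  )
  for (cp in config$coupling) {
    rows <- which(is_pd & subjects$subtype == cp$group)
    if (length(rows) < 3L) next
    hemi <- vapply(rows, function(i) {
      map <- lateralize_measures(0L, 1L, subjects$onset_side[i])
      h <- if (cp$hemisphere == "MAS") map$mas_hemisphere
           else .contralateral(map$mas_hemisphere)
      h
    }, character(1))
    iron <- iron_levels[cbind(rows, match(paste0(cp$nucleus, "_", hemi),
                                          colnames(iron_levels)))]
    z <- (iron - mean(iron)) / stats::sd(iron)
    latent[[cp$score]][rows] <- cp$r * z +
      sqrt(1 - cp$r^2) * stats::rnorm(length(rows))
  }

  updrs <- .round_clip(33 + 12 * latent$updrs3_total, 0, 132)
  subjects$updrs3_total <- ifelse(is_pd, updrs, NA_real_)
  mas_frac <- stats::runif(n, 0.32, 0.42)
  las_frac <- stats::runif(n, 0.20, 0.30)
  subjects$updrs3_mas <- ifelse(is_pd, round(updrs * mas_frac), NA_real_)
  subjects$updrs3_las <- ifelse(is_pd, round(updrs * las_frac), NA_real_)

  hy <- .round_clip(ifelse(subjects$subtype == "PIGD", 2.3, 1.9) +
                      0.7 * latent$hy, 1, 5, step = 0.5)
  subjects$hy <- ifelse(is_pd, hy, NA_real_)

  # item scores: PIGD total driven by its latent for coupled subjects
  rule <- subtype_rule()
  tremor_mat <- matrix(NA_integer_, n, rule$n_tremor)
  pigd_mat <- matrix(NA_integer_, n, rule$n_pigd)
  for (i in seq_len(n)) {
    if (!is_pd[i]) next
    base_p <- if (subjects$subtype[i] == "PIGD") 5.5 else 2
    sd_p <- if (subjects$subtype[i] == "PIGD") 2.5 else 1.2
    pigd_total <- as.integer(.round_clip(base_p + sd_p * latent$pigd_score[i],
                                         0, rule$n_pigd * 4L))
    it <- .draw_items(subjects$subtype[i], pigd_total, rule)
    tremor_mat[i, ] <- it$tremor
    pigd_mat[i, ] <- it$pigd
  }
  colnames(tremor_mat) <- paste0("tremor_", seq_len(rule$n_tremor))
  colnames(pigd_mat) <- paste0("pigd_", seq_len(rule$n_pigd))
  subjects <- cbind(subjects, tremor_mat, pigd_mat)
  subjects$tremor_score <- rowSums(tremor_mat)
  subjects$pigd_score <- rowSums(pigd_mat)
  subjects
}

#' Generate a complete synthetic cohort
#'
#' Pure construction (writes nothing): builds the shared nucleus geometry,
#' draws the subject table (groups, subtypes, stages, durations, onset
#' sides, demographics, clinical scores coupled to regional iron) and,
#' unless `volumes = FALSE`, one susceptibility volume per subject. A fixed
#' (config, seed) pair regenerates the bundle bit-identically.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @param volumes Generate voxel volumes (set FALSE for fast subject-level
#'   simulation studies that only need regional means).
#' @param geometry Optional precomputed [cohort_geometry()] for this config,
#'   to avoid re-rasterising masks in repeated-simulation studies (geometry
#'   is deterministic, so this never changes the result).
#' @return Object of class `qsm_cohort`: `subjects`, `iron_levels` (true
#'   subject-level regional means, n x 6), `volumes` (list or NULL),
#'   `geometry`, `affine`, `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed,
                            volumes = TRUE, geometry = NULL) {
  .validate_config(config)
  geom <- if (is.null(geometry)) cohort_geometry(config) else geometry

  set.seed(seed)
  gs <- config$group_sizes
  rows <- list()
  add <- function(group, subtype, stage, k) {
    if (k > 0)
      rows[[length(rows) + 1L]] <<- data.frame(
        group = group, subtype = subtype, stage = stage, n = k,
        stringsAsFactors = FALSE)
  }
  add("HC", "none", "none", gs[["HC"]])
  for (st in c("PIGD", "TD")) {
    if (is.na(gs[st])) next
    sz <- config$stage_sizes[[st]]
    for (sg in c("early", "middle", "late")) add("PD", st, sg, sz[[sg]])
  }
  blocks <- do.call(rbind, rows)
  subjects <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(b) {
    data.frame(group = rep(blocks$group[b], blocks$n[b]),
               subtype = rep(blocks$subtype[b], blocks$n[b]),
               stage = rep(blocks$stage[b], blocks$n[b]),
               stringsAsFactors = FALSE)
  }))
  n <- nrow(subjects)
  subjects <- cbind(id = sprintf("sub-%03d", seq_len(n)), subjects,
                    stringsAsFactors = FALSE)

  is_pd <- subjects$group == "PD"
  dur <- rep(NA_real_, n)
  dur[is_pd & subjects$stage == "early"] <-
    round(stats::runif(sum(is_pd & subjects$stage == "early"), 0.3, 1.9), 2)
  dur[is_pd & subjects$stage == "middle"] <-
    round(stats::runif(sum(is_pd & subjects$stage == "middle"), 2, 6), 2)
  dur[is_pd & subjects$stage == "late"] <-
    round(stats::runif(sum(is_pd & subjects$stage == "late"), 6.1, 12), 2)
  subjects$disease_duration <- dur
  subjects$onset_side <- ifelse(is_pd,
                                ifelse(stats::runif(n) < 25 / 55, "R", "L"),
                                NA_character_)
  subjects$handedness <- ifelse(is_pd, NA_character_, "R")

  # subject-level true regional means: hemisphere-mapped baseline + subtype/
  # stage offset + per-nucleus subject random effect
  mask_names <- names(geom$masks)
  iron <- matrix(NA_real_, n, length(mask_names),
                 dimnames = list(NULL, mask_names))
  for (i in seq_len(n)) {
    side <- if (is_pd[i]) subjects$onset_side[i] else subjects$handedness[i]
    mas_hemi <- .contralateral(side)
    off <- if (is_pd[i])
      config$stage_offsets[[subjects$subtype[i]]][[subjects$stage[i]]] else 0
    for (nm in mask_names) {
      m <- geom$masks[[nm]]
      col <- if (m$hemisphere == mas_hemi) "MAS" else "LAS"
      iron[i, nm] <- config$baselines[m$name, col] + off +
        stats::rnorm(1, 0, config$subject_sd[[m$name]])
    }
  }

  subjects <- generate_clinical_scores(subjects, iron, config)

  # HC carry no motor items
  item_cols <- grep("^(tremor|pigd)_[0-9]+$|^(tremor|pigd)_score$",
                    names(subjects), value = TRUE)
  subjects[!is_pd, item_cols] <- NA

  vols <- NULL
  if (volumes) {
    vols <- vector("list", n)
    names(vols) <- subjects$id
    for (i in seq_len(n)) {
      vols[[i]] <- generate_qsm_volume(geom, config, iron[i, ],
                                       stage = subjects$stage[i])
    }
  }

  structure(list(subjects = subjects, iron_levels = iron, volumes = vols,
                 geometry = geom, affine = geom$affine, config = config,
                 seed = as.integer(seed)),
            class = "qsm_cohort")
}

#' @export
print.qsm_cohort <- function(x, ...) {
  tab <- table(paste(x$subjects$group,
                     ifelse(x$subjects$subtype == "none", "",
                            x$subjects$subtype)))
  cat("Synthetic QSM cohort: ", nrow(x$subjects), " subjects (seed ",
      x$seed, ")\n", sep = "")
  print(tab)
  cat("grid ", paste(x$config$grid_shape, collapse = " x "), ", voxel ",
      paste(x$config$voxel_size, collapse = " x "), " mm, ",
      length(x$geometry$masks), " ROI masks",
      if (is.null(x$volumes)) " (no volumes generated)" else "", "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.qsm_cohort <- function(object, ...) {
  s <- object$subjects
  data.frame(
    group = c("HC", "PIGD", "TD"),
    n = c(sum(s$group == "HC"), sum(s$subtype == "PIGD"),
          sum(s$subtype == "TD")),
    age_mean = vapply(list(s$group == "HC", s$subtype == "PIGD",
                           s$subtype == "TD"),
                      function(i) mean(s$age[i]), numeric(1)))
}
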