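.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

.write_provenance <- function(out_dir, config, seed, extra = list()) {
  prov <- c(list(package = "qsmgrad",
                 version = as.character(utils::packageVersion("qsmgrad")),
                 r_version = paste(R.version$major, R.version$minor,
                                   sep = "."),
                 seed = seed,
                 config_hash = config_hash(config)),
            extra)
  yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))
}

#' Simulate a cohort and write it to disk
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (defaults to the config's).
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
run_simulate <- function(config = cohort_config(), seed = config$seed,
                         out_dir) {
  cohort <- generate_cohort(config, seed = seed, volumes = TRUE)
  write_cohort(cohort, out_dir)
  .write_provenance(out_dir, config, seed, list(step = "simulate"))
  invisible(out_dir)
}

# read the label volume + map from a cohort directory and rebuild roi_mask
# objects (0-based lexicographic indices)
.read_label_masks <- function(data_dir) {
  lab <- read_qsm_volume(file.path(data_dir, "labels.nii.gz"))
  map <- utils::read.delim(file.path(data_dir, "label_map.tsv"),
                           stringsAsFactors = FALSE)
  masks <- list()
  for (r in seq_len(nrow(map))) {
    lin <- which(lab$data == map$label[r])
    if (!length(lin))
      stop("label ", map$label[r], " is empty in the label volume")
    gs <- dim(lab$data)
    lin0 <- lin - 1L
    idx <- cbind(lin0 %% gs[1],
                 (lin0 %/% gs[1]) %% gs[2],
                 lin0 %/% (gs[1] * gs[2]))
    ord <- order(idx[, 1], idx[, 2], idx[, 3])
    idx <- idx[ord, , drop = FALSE]
    storage.mode(idx) <- "integer"
    nm <- paste0(map$nucleus[r], "_", map$hemisphere[r])
    masks[[nm]] <- structure(
      list(label = map$label[r], name = map$nucleus[r],
           hemisphere = map$hemisphere[r], indices = idx,
           affine = lab$affine, n_voxels = nrow(idx)),
      class = "roi_mask")
  }
  list(masks = masks, label_volume = lab, map = map)
}

#' Compute and write principal axis frames for every labeled ROI
#'
#' @param data_dir Cohort directory (from [run_simulate()] or real data laid
#'   out the same way).
#' @param out_dir Output directory.
#' @return Named list of labeled `axis_frame`s, invisibly.
#' @export
run_axes <- function(data_dir, out_dir = data_dir) {
  lm <- .read_label_masks(data_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  frames <- lapply(lm$masks, function(m)
    label_axes_anatomically(compute_principal_axes(m), m$hemisphere))
  rows <- lapply(names(frames), function(nm) {
    f <- frames[[nm]]
    m <- lm$masks[[nm]]
    do.call(rbind, lapply(1:3, function(a) data.frame(
      label = m$label, nucleus = m$name, hemisphere = m$hemisphere,
      n_voxels = m$n_voxels,
      centroid_x = f$centroid[1], centroid_y = f$centroid[2],
      centroid_z = f$centroid[3],
      axis = f$labels[a], singular_value = f$singular_values[a],
      ax = f$axes[1, a], ay = f$axes[2, a], az = f$axes[3, a],
      label_tie = f$label_tie, stringsAsFactors = FALSE)))
  })
  .write_tsv(do.call(rbind, rows), file.path(out_dir, "axes.tsv"))
  invisible(frames)
}

#' Compute and write per-subject spatial functions
#'
#' For every subject volume and every labeled ROI: per-segment median
#' susceptibility along the three labeled principal axes, plus the ROI mean.
#' Writes `spatial_functions.tsv` (long format), `roi_means.tsv` and a
#' structured `spatial_functions.json`.
#'
#' @param data_dir Cohort directory.
#' @param out_dir Output directory.
#' @param n_segments Segments per axis (default 7).
#' @return Invisibly, the long-format data frame.
#' @export
run_gradients <- function(data_dir, out_dir = data_dir, n_segments = 7L) {
  lm <- .read_label_masks(data_dir)
  subjects <- utils::read.delim(file.path(data_dir, "subjects.tsv"),
                                stringsAsFactors = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  frames <- lapply(lm$masks, function(m)
    label_axes_anatomically(compute_principal_axes(m), m$hemisphere))

  long <- list(); means <- list(); jdoc <- list()
  for (id in subjects$id) {
    vol <- read_qsm_volume(file.path(data_dir, paste0(id, "_qsm.nii.gz")))
    check_same_grid(vol, lm$label_volume)
    for (nm in names(lm$masks)) {
      sf <- compute_spatial_function(vol$data, lm$masks[[nm]], frames[[nm]],
                                     n = n_segments)
      sf$subject <- id
      m <- lm$masks[[nm]]
      for (ax in rownames(sf$medians)) {
        long[[length(long) + 1L]] <- data.frame(
          subject = id, roi = m$name, hemisphere = m$hemisphere, axis = ax,
          segment = seq_len(n_segments),
          median = unname(sf$medians[ax, ]),
          n_voxels = unname(sf$counts[ax, ]), stringsAsFactors = FALSE)
      }
      means[[length(means) + 1L]] <- data.frame(
        subject = id, roi = m$name, hemisphere = m$hemisphere,
        mean = sf$roi_mean, stringsAsFactors = FALSE)
      jdoc[[id]][[nm]] <- list(roi = m$name, hemisphere = m$hemisphere,
                               n = n_segments,
                               medians = apply(sf$medians, 1, as.numeric,
                                               simplify = FALSE),
                               counts = apply(sf$counts, 1, as.numeric,
                                              simplify = FALSE),
                               roi_mean = sf$roi_mean)
    }
  }
  long <- do.call(rbind, long)
  means <- do.call(rbind, means)
  .write_tsv(long, file.path(out_dir, "spatial_functions.tsv"))
  .write_tsv(means, file.path(out_dir, "roi_means.tsv"))
  jsonlite::write_json(jdoc, file.path(out_dir, "spatial_functions.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(long)
}

# attach MAS/LAS side to a table keyed by subject + hemisphere
.lateralize_table <- function(df, subjects) {
  side <- ifelse(subjects$group == "PD", subjects$onset_side,
                 subjects$handedness)
  mas_hemi <- stats::setNames(.contralateral(side), subjects$id)
  df$side <- ifelse(df$hemisphere == mas_hemi[df$subject], "MAS", "LAS")
  df
}

.sex01 <- function(sex) as.numeric(sex == "M")

.stage_factor <- function(subjects) {
  factor(ifelse(subjects$group == "HC", "HC", subjects$stage),
         levels = c("HC", "early", "middle", "late"))
}

#' Covariate-adjusted group comparisons of regional iron
#'
#' Runs the general linear models with age, sex and LEDD as covariates:
#' mean regional susceptibility for HC vs PD, HC vs PIGD vs TD, and HC vs
#' the three disease stages within each subtype; and per-segment models of
#' the stage comparison for every ROI, side and axis. Pairwise contrasts are
#' Bonferroni-adjusted within the family recorded in the output (3 pairwise
#' contrasts per ROI x side for the mean models; the n segments of an ROI x
#' side x axis for the segment-level omnibus tests). Every table carries the
#' config hash from the cohort's provenance.
#'
#' @param data_dir Cohort directory (subject table).
#' @param gradients_dir Directory holding `roi_means.tsv` and
#'   `spatial_functions.tsv` (defaults to `data_dir`).
#' @param out_dir Output directory.
#' @param covariates Covariate column names (default age, sex, ledd).
#' @return Invisibly, a list of the result data frames.
#' @export
run_compare <- function(data_dir, gradients_dir = data_dir,
                        out_dir = data_dir,
                        covariates = c("age", "sex", "ledd")) {
  subjects <- utils::read.delim(file.path(data_dir, "subjects.tsv"),
                                stringsAsFactors = FALSE)
  means <- utils::read.delim(file.path(gradients_dir, "roi_means.tsv"),
                             stringsAsFactors = FALSE)
  segs <- utils::read.delim(file.path(gradients_dir, "spatial_functions.tsv"),
                            stringsAsFactors = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  chash <- tryCatch(
    yaml::read_yaml(file.path(data_dir, "provenance.yaml"))$config_hash,
    error = function(e) NA_character_)

  means <- .lateralize_table(means, subjects)
  segs <- .lateralize_table(segs, subjects)
  covs <- data.frame(age = subjects$age, sex = .sex01(subjects$sex),
                     ledd = ifelse(is.na(subjects$ledd), 0, subjects$ledd))
  covs <- covs[, intersect(covariates, names(covs)), drop = FALSE]
  rownames(covs) <- subjects$id

  grp_pd <- factor(subjects$group, levels = c("HC", "PD"))
  grp_sub <- factor(ifelse(subjects$group == "HC", "HC", subjects$subtype),
                    levels = c("HC", "PIGD", "TD"))

  mean_rows <- list()
  add_mean <- function(model, roi, side, fit, extra_keys = list()) {
    ct <- fit$contrasts
    mean_rows[[length(mean_rows) + 1L]] <<- data.frame(
      model = model, roi = roi, side = side,
      comparison = "omnibus", estimate = NA_real_,
      statistic = fit$statistic, df1 = fit$df[1], df2 = fit$df[2],
      p_raw = fit$p_value, p_adjusted = NA_real_,
      family = NA_character_, family_size = NA_integer_,
      n_dropped = fit$n_dropped, config_hash = chash,
      stringsAsFactors = FALSE)
    fam <- paste0(model, ":", roi, ":", side)
    mean_rows[[length(mean_rows) + 1L]] <<- data.frame(
      model = model, roi = roi, side = side,
      comparison = paste(ct$group2, "vs", ct$group1),
      estimate = ct$estimate, statistic = ct$t, df1 = NA_real_, df2 = ct$df,
      p_raw = ct$p_raw, p_adjusted = ct$p_adjusted,
      family = fam, family_size = ct$family_size,
      n_dropped = fit$n_dropped, config_hash = chash,
      stringsAsFactors = FALSE)
  }

  for (roi in unique(means$roi)) {
    for (sd_ in c("MAS", "LAS")) {
      sel <- means[means$roi == roi & means$side == sd_, ]
      y <- sel$mean[match(subjects$id, sel$subject)]
      add_mean("HC_vs_PD", roi, sd_,
               glm_adjusted_comparison(y, grp_pd, covs))
      add_mean("HC_PIGD_TD", roi, sd_,
               glm_adjusted_comparison(y, grp_sub, covs))
      for (st in c("PIGD", "TD")) {
        in_model <- subjects$group == "HC" | subjects$subtype == st
        add_mean(paste0("stages_", st), roi, sd_,
                 glm_adjusted_comparison(y[in_model],
                                         .stage_factor(subjects)[in_model],
                                         covs[in_model, , drop = FALSE]))
      }
    }
  }
  compare_mean <- do.call(rbind, mean_rows)
  .write_tsv(compare_mean, file.path(out_dir, "compare_mean.tsv"))

  seg_rows <- list()
  n_seg <- max(segs$segment)
  for (st in c("PIGD", "TD")) {
    in_model <- subjects$group == "HC" | subjects$subtype == st
    ids <- subjects$id[in_model]
    gstage <- .stage_factor(subjects)[in_model]
    cv <- covs[in_model, , drop = FALSE]
    for (roi in unique(segs$roi)) {
      for (sd_ in c("MAS", "LAS")) {
        for (ax in unique(segs$axis)) {
          fam <- paste0("stages_", st, ":", roi, ":", sd_, ":", ax)
          block <- segs[segs$roi == roi & segs$side == sd_ &
                          segs$axis == ax, ]
          praw <- fstat <- rep(NA_real_, n_seg)
          dropped <- rep(NA_integer_, n_seg)
          for (s in seq_len(n_seg)) {
            bs <- block[block$segment == s, ]
            y <- bs$median[match(ids, bs$subject)]
            if (sum(!is.na(y)) < length(levels(gstage)) + ncol(cv) + 2) next
            fit <- glm_adjusted_comparison(y, gstage, cv)
            praw[s] <- fit$p_value
            fstat[s] <- fit$statistic
            dropped[s] <- fit$n_dropped
          }
          ok <- !is.na(praw)
          padj <- rep(NA_real_, n_seg)
          padj[ok] <- pmin(1, praw[ok] * n_seg)   # Bonferroni over segments
          seg_rows[[length(seg_rows) + 1L]] <- data.frame(
            model = paste0("stages_", st), roi = roi, side = sd_, axis = ax,
            segment = seq_len(n_seg), statistic = fstat, p_raw = praw,
            p_adjusted = padj, family = fam, family_size = n_seg,
            n_dropped = dropped, config_hash = chash,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  compare_segments <- do.call(rbind, seg_rows)
  .write_tsv(compare_segments, file.path(out_dir, "compare_segments.tsv"))
  invisible(list(mean = compare_mean, segments = compare_segments))
}

#' Partial correlations between regional iron and clinical scores
#'
#' Within each motor subtype: partial correlation (age as covariate) of each
#' lateralized mean regional susceptibility with each clinical score,
#' Benjamini-Hochberg adjusted across the ROI x score grid within the
#' subtype (family recorded per row).
#'
#' @param data_dir Cohort directory.
#' @param gradients_dir Directory holding `roi_means.tsv`.
#' @param out_dir Output directory.
#' @param scores Clinical score columns to correlate.
#' @return Invisibly, the result data frame.
#' @export
run_correlate <- function(data_dir, gradients_dir = data_dir,
                          out_dir = data_dir,
                          scores = c("tremor_score", "pigd_score",
                                     "updrs3_total", "updrs3_mas",
                                     "updrs3_las", "hy")) {
  subjects <- utils::read.delim(file.path(data_dir, "subjects.tsv"),
                                stringsAsFactors = FALSE)
  means <- utils::read.delim(file.path(gradients_dir, "roi_means.tsv"),
                             stringsAsFactors = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  chash <- tryCatch(
    yaml::read_yaml(file.path(data_dir, "provenance.yaml"))$config_hash,
    error = function(e) NA_character_)
  means <- .lateralize_table(means, subjects)

  rows <- list()
  for (st in c("PIGD", "TD")) {
    sub <- subjects[subjects$group == "PD" & subjects$subtype == st, ]
    for (roi in unique(means$roi)) {
      for (sd_ in c("MAS", "LAS")) {
        sel <- means[means$roi == roi & means$side == sd_, ]
        iron <- sel$mean[match(sub$id, sel$subject)]
        for (sc in scores) {
          if (!sc %in% names(sub)) next
          res <- partial_correlation(iron, sub[[sc]],
                                     data.frame(age = sub$age))
          rows[[length(rows) + 1L]] <- data.frame(
            subtype = st, roi = roi, side = sd_, score = sc,
            r = res$estimate, df = res$df, p_raw = res$p_value,
            n = res$n, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  out$family <- paste0("fdr:", out$subtype)
  for (st in unique(out$subtype)) {
    i <- out$subtype == st
    out$p_adjusted[i] <- adjust_pvalues(out$p_raw[i], "BH")
  }
  out$config_hash <- chash
  .write_tsv(out, file.path(out_dir, "correlations.tsv"))
  invisible(out)
}

#' Best-effort summary report with figures
#'
#' Writes group-averaged spatial-function plots (one PNG per ROI and side)
#' and a peak-trajectory table. Plot generation is a convenience layer on
#' top of the tabular outputs.
#'
#' @param data_dir Cohort directory.
#' @param gradients_dir Directory holding `spatial_functions.tsv`.
#' @param out_dir Output directory.
#' @return Invisibly, the peak-trajectory data frame.
#' @export
run_report <- function(data_dir, gradients_dir = data_dir,
                       out_dir = data_dir) {
  subjects <- utils::read.delim(file.path(data_dir, "subjects.tsv"),
                                stringsAsFactors = FALSE)
  segs <- utils::read.delim(file.path(gradients_dir, "spatial_functions.tsv"),
                            stringsAsFactors = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  segs <- .lateralize_table(segs, subjects)
  glab <- stats::setNames(
    ifelse(subjects$group == "HC", "HC",
           paste0(subjects$subtype, "-", substr(subjects$stage, 1, 1))),
    subjects$id)
  segs$glab <- glab[segs$subject]
  n_seg <- max(segs$segment)

  traj_rows <- list()
  for (st in c("PIGD", "TD")) {
    stages <- paste0(st, "-", c("e", "m", "l"))
    for (roi in unique(segs$roi)) {
      for (sd_ in c("MAS", "LAS")) {
        for (ax in unique(segs$axis)) {
          block <- segs[segs$roi == roi & segs$side == sd_ &
                          segs$axis == ax & segs$glab %in% stages, ]
          gm <- vapply(stages, function(g) vapply(seq_len(n_seg), function(s)
            mean(block$median[block$glab == g & block$segment == s],
                 na.rm = TRUE), numeric(1)), numeric(n_seg))
          if (any(colSums(!is.na(gm)) == 0)) next  # a stage with no data
          gfs <- lapply(stages, function(g) structure(
            list(group = g,
                 mean = matrix(gm[, g], 1, n_seg, dimnames = list(ax, NULL)),
                 n = n_seg, roi = roi), class = "group_spatial_function"))
          tr <- peak_trajectory(gfs, ax)
          traj_rows[[length(traj_rows) + 1L]] <- data.frame(
            subtype = st, roi = roi, side = sd_, axis = ax,
            peaks = paste(tr$peaks$peak, collapse = "->"),
            shifts = paste(tr$shifts, collapse = "; "),
            stringsAsFactors = FALSE)
          fp <- file.path(out_dir, sprintf("gradient_%s_%s_%s_%s.png",
                                           st, roi, sd_, gsub("-", "", ax)))
          grDevices::png(fp, width = 600, height = 450)
          graphics::matplot(seq_len(n_seg), gm, type = "b", pch = 16,
                            lty = 1, xlab = paste(ax, "segment"),
                            ylab = "median susceptibility",
                            main = paste(roi, sd_, ax))
          graphics::legend("topleft", legend = stages,
                           col = seq_along(stages), lty = 1, pch = 16,
                           bty = "n")
          grDevices::dev.off()
        }
      }
    }
  }
  traj <- do.call(rbind, traj_rows)
  .write_tsv(traj, file.path(out_dir, "peak_trajectories.tsv"))
  invisible(traj)
}

#' Run the full pipeline end to end
#'
#' `simulate -> axes -> gradients -> compare -> correlate` into one output
#' directory.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param report Also produce the best-effort figures.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = cohort_config(), seed = config$seed,
                         out_dir, report = FALSE) {
  run_simulate(config, seed, out_dir)
  run_axes(out_dir)
  run_gradients(out_dir, n_segments = config$n_segments)
  run_compare(out_dir)
  run_correlate(out_dir)
  if (report) run_report(out_dir)
  invisible(out_dir)
}
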