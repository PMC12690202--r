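# Shared fixtures: everything is generated in code at test time.

# independent median: sort-based, midpoint of central pair for even counts
oracle_median <- function(v) {
  v <- sort(v)
  k <- length(v)
  if (k %% 2 == 1) v[(k + 1) / 2] else (v[k / 2] + v[k / 2 + 1]) / 2
}

# a small axis-aligned block mask (0-based indices) on a unit grid
block_mask <- function(nx = 9, ny = 5, nz = 3, voxel = c(1, 1, 1),
                       origin = c(0, 0, 0)) {
  idx <- as.matrix(expand.grid(i = 0:(nx - 1), j = 0:(ny - 1),
                               k = 0:(nz - 1)))
  idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), ]
  dimnames(idx) <- NULL
  storage.mode(idx) <- "integer"
  structure(list(label = 1L, name = "block", hemisphere = "R",
                 indices = idx, affine = make_affine(voxel, origin),
                 n_voxels = nrow(idx)),
            class = "roi_mask")
}

# a small cohort configuration (paper-structured but few subjects)
tiny_config <- function(hc = 6, pigd = 6, td = 6, ...) {
  third <- function(n) c(early = n %/% 3, middle = n %/% 3,
                         late = n - 2 * (n %/% 3))
  cohort_config(group_sizes = c(HC = hc, PIGD = pigd, TD = td),
                stage_sizes = list(PIGD = third(pigd), TD = third(td)), ...)
}

# MAS hemisphere of each subject (contralateral to onset / dominant hand)
mas_hemisphere <- function(subjects) {
  side <- ifelse(subjects$group == "PD", subjects$onset_side,
                 subjects$handedness)
  ifelse(side == "R", "L", "R")
}

# subject-level lateralized iron from a cohort's true regional means
lateralized_iron <- function(cohort, nucleus, side = c("MAS", "LAS")) {
  side <- match.arg(side)
  mh <- mas_hemisphere(cohort$subjects)
  hemi <- if (side == "MAS") mh else ifelse(mh == "L", "R", "L")
  cohort$iron_levels[cbind(seq_len(nrow(cohort$subjects)),
                           match(paste0(nucleus, "_", hemi),
                                 colnames(cohort$iron_levels)))]
}

# standard covariate frame from a subject table (sex coded 0/1)
covariate_frame <- function(subjects) {
  data.frame(age = subjects$age, sex = as.numeric(subjects$sex == "M"),
             ledd = ifelse(is.na(subjects$ledd), 0, subjects$ledd))
}

# stage factor with HC reference
stage_factor <- function(subjects) {
  factor(ifelse(subjects$group == "HC", "HC", subjects$stage),
         levels = c("HC", "early", "middle", "late"))
}
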