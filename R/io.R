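#' Read a 3D NIfTI volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return List with `data` (3D numeric array) and `affine` (4x4 voxel-to-mm
#'   matrix, 0-based indexing).
#' @export
read_qsm_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D volume, got ", length(dim(img)), "D: ", path)
  aff <- structure(RNifti::xform(img), class = NULL)
  list(data = array(as.numeric(img), dim = dim(img)),
       affine = matrix(as.numeric(aff), 4, 4))
}

#' Write a 3D volume as NIfTI
#'
#' Round-trips bitwise through [read_qsm_volume()] for the "double" datatype.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-mm affine.
#' @param path Output path (`.nii` or `.nii.gz`; compression follows the
#'   extension).
#' @param datatype NIfTI storage type: "double", "float" or "int16".
#' @export
write_qsm_volume <- function(data, affine, path, datatype = "double") {
  img <- RNifti::asNifti(data, datatype = datatype)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

.affines_match <- function(a, b, tol = 1e-4) {
  max(abs(a - b)) <= tol
}

#' Check that a map and a mask share grid and affine
#'
#' @param map,mask Lists as returned by [read_qsm_volume()].
#' @return Invisibly TRUE; errors with both affines printed on mismatch.
#' @export
check_same_grid <- function(map, mask) {
  if (!identical(dim(map$data), dim(mask$data)))
    stop("grid mismatch: map is ", paste(dim(map$data), collapse = "x"),
         ", mask is ", paste(dim(mask$data), collapse = "x"))
  if (!.affines_match(map$affine, mask$affine))
    stop("affine mismatch between map and mask:\nmap affine:\n",
         paste(utils::capture.output(print(map$affine)), collapse = "\n"),
         "\nmask affine:\n",
         paste(utils::capture.output(print(mask$affine)), collapse = "\n"))
  invisible(TRUE)
}

.mandatory_subject_cols <- c("id", "group", "subtype", "stage",
                             "disease_duration", "onset_side", "age", "sex",
                             "ledd")

#' Read a subject metadata table
#'
#' Tab-separated table with one row per participant. Mandatory columns:
#' `id`, `group`, `subtype`, `stage`, `disease_duration`, `onset_side`,
#' `age`, `sex`, `ledd`. Unknown columns are preserved untouched. PD rows
#' (group == "PD") must carry a duration and an onset side; validation
#' errors name the offending row.
#'
#' @param path Path to a TSV file.
#' @return Data frame of typed subject records.
#' @export
read_subject_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  missing_cols <- setdiff(.mandatory_subject_cols, names(tab))
  if (length(missing_cols))
    stop("subject table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  tab$disease_duration <- as.numeric(tab$disease_duration)
  tab$age <- as.numeric(tab$age)
  tab$ledd <- as.numeric(tab$ledd)
  pd <- which(tab$group == "PD")
  bad_dur <- pd[is.na(tab$disease_duration[pd])]
  if (length(bad_dur))
    stop("PD row(s) without disease duration: row ",
         paste(bad_dur, collapse = ", "))
  bad_side <- pd[is.na(tab$onset_side[pd]) |
                   !tab$onset_side[pd] %in% c("R", "L")]
  if (length(bad_side))
    stop("PD row(s) without a valid onset side: row ",
         paste(bad_side, collapse = ", "))
  message("read ", nrow(tab), " subject records from ", basename(path))
  tab
}

#' Write a subject table as TSV
#'
#' @param subjects Data frame.
#' @param path Output path.
#' @export
write_subject_table <- function(subjects, path) {
  utils::write.table(subjects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# ---- config serialization (YAML, same schema as the CLI input) ----------

config_to_list <- function(cfg) {
  list(
    group_sizes = as.list(cfg$group_sizes),
    stage_sizes = lapply(cfg$stage_sizes, as.list),
    grid_shape = as.integer(cfg$grid_shape),
    voxel_size = as.numeric(cfg$voxel_size),
    nuclei = lapply(cfg$nuclei, function(s) list(
      name = s$name, hemisphere = s$hemisphere,
      semi_axes = as.numeric(s$semi_axes), center = as.numeric(s$center),
      rotation = as.numeric(s$rotation))),
    baselines = list(values = as.numeric(cfg$baselines),
                     rows = rownames(cfg$baselines),
                     cols = colnames(cfg$baselines)),
    gradients = lapply(cfg$gradients, function(g) list(
      axis = g$axis, peak = g$peak, amplitude = g$amplitude,
      width_segments = g$width_segments,
      peak_by_stage = if (is.null(g$peak_by_stage)) NULL
                      else as.list(g$peak_by_stage))),
    stage_offsets = lapply(cfg$stage_offsets, as.list),
    subject_sd = as.list(cfg$subject_sd),
    noise_sd = cfg$noise_sd,
    coupling = cfg$coupling,
    n_segments = cfg$n_segments,
    seed = cfg$seed)
}

config_from_list <- function(x) {
  cohort_config(
    group_sizes = unlist(x$group_sizes),
    stage_sizes = lapply(x$stage_sizes, unlist),
    grid_shape = x$grid_shape,
    voxel_size = x$voxel_size,
    nuclei = lapply(x$nuclei, function(s) nucleus_shape(
      s$name, s$hemisphere, s$semi_axes, s$center,
      matrix(s$rotation, 3, 3))),
    baselines = matrix(x$baselines$values,
                       length(x$baselines$rows), length(x$baselines$cols),
                       dimnames = list(x$baselines$rows, x$baselines$cols)),
    gradients = lapply(x$gradients, function(g) list(
      axis = g$axis, peak = g$peak, amplitude = g$amplitude,
      width_segments = g$width_segments,
      peak_by_stage = if (is.null(g$peak_by_stage)) NULL
                      else unlist(g$peak_by_stage))),
    stage_offsets = lapply(x$stage_offsets, unlist),
    subject_sd = unlist(x$subject_sd),
    noise_sd = x$noise_sd,
    coupling = x$coupling,
    n_segments = x$n_segments,
    seed = x$seed)
}

#' Write / read a cohort configuration as YAML
#'
#' The on-disk schema is the same one the command-line interface accepts, so
#' a provenance file regenerates its cohort bit-identically.
#'
#' @param config A [cohort_config()].
#' @param path YAML path.
#' @return `write_cohort_config` the path; `read_cohort_config` the config.
#' @export
write_cohort_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path, precision = 17L)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  config_from_list(yaml::read_yaml(path))
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical JSON rendering; stamped into every output table so
#' results can be traced to the configuration that produced them.
#'
#' @param config A [cohort_config()] (or any serialisable list).
#' @return Character MD5 digest.
#' @export
config_hash <- function(config) {
  x <- if (inherits(config, "cohort_config")) config_to_list(config)
       else config
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Write a generated cohort to disk
#'
#' NIfTI volumes per subject (`<id>_qsm.nii.gz`), one shared integer label
#' mask (`labels.nii.gz`), the subject table (`subjects.tsv`), the label map
#' (`label_map.tsv`) and the provenance config (`config.yaml`, which
#' together with the seed regenerates the cohort).
#'
#' @param cohort A `qsm_cohort` with volumes.
#' @param dir Output directory (created if needed).
#' @param datatype NIfTI datatype for the susceptibility volumes.
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir, datatype = "float") {
  stopifnot(inherits(cohort, "qsm_cohort"))
  if (is.null(cohort$volumes))
    stop("cohort was generated without volumes; nothing to write")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$volumes))
    write_qsm_volume(cohort$volumes[[id]], cohort$affine,
                     file.path(dir, paste0(id, "_qsm.nii.gz")),
                     datatype = datatype)
  write_qsm_volume(cohort$geometry$label_array, cohort$affine,
                   file.path(dir, "labels.nii.gz"), datatype = "int16")
  write_subject_table(cohort$subjects, file.path(dir, "subjects.tsv"))
  utils::write.table(cohort$geometry$label_map,
                     file.path(dir, "label_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  cfg$seed <- cohort$seed
  write_cohort_config(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
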