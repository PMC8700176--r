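# Serialization: phantoms and image volumes as NIfTI + JSON sidecars,
# patch stores and model checkpoints as RDS + JSON manifests, metric
# reports as JSON/CSV.

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}

nifti_with_voxels <- function(data, voxel_size_mm, datatype) {
  RNifti::asNifti(data, datatype = datatype,
                  pixdim = rep(voxel_size_mm, 3))
}

#' Write a phantom as paired NIfTI files plus a JSON sidecar
#'
#' Produces `<config_id>_activity.nii` (float32, Bq/mL),
#' `<config_id>_labels.nii` (int16) and `<config_id>.json`.
#'
#' @param phantom A `voxel_phantom`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the sidecar path.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, phantom$config_id)
  RNifti::writeNifti(nifti_with_voxels(phantom$activity,
                                       phantom$voxel_size_mm, "float"),
                     paste0(base, "_activity.nii"))
  RNifti::writeNifti(nifti_with_voxels(phantom$labels,
                                       phantom$voxel_size_mm, "int16"),
                     paste0(base, "_labels.nii"))
  meta <- phantom$meta
  meta$rod_centers_mm <- NULL
  side <- list(config_id = phantom$config_id, family = phantom$family,
               tbr = phantom$tbr, voxel_size_mm = phantom$voxel_size_mm,
               dim = dim(phantom$activity),
               total_activity_bq = phantom_total_activity(phantom),
               regions = phantom$regions,
               meta = meta)
  write_json_file(side, paste0(base, ".json"))
  invisible(paste0(base, ".json"))
}

#' Read a phantom written by [write_phantom()]
#' @param path The JSON sidecar path.
#' @return A `voxel_phantom`.
#' @export
read_phantom <- function(path) {
  side <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- sub("\\.json$", "", path)
  act <- array(as.numeric(RNifti::readNifti(paste0(base, "_activity.nii"))),
               side$dim)
  lab <- array(as.integer(RNifti::readNifti(paste0(base, "_labels.nii"))),
               side$dim)
  grid <- phantom_grid(side$dim[1], side$dim[3], side$voxel_size_mm)
  regions <- if (!is.null(side$regions)) tibble::as_tibble(side$regions)
  new_voxel_phantom(act, lab, grid, side$family, side$config_id,
                    tbr = side$tbr, regions = regions,
                    meta = as.list(side$meta))
}

#' Write an image volume as NIfTI (float32) plus a JSON sidecar
#' @param img An `image_volume`.
#' @param dir Output directory.
#' @param name File stem; defaults to `<config_id>_<provenance>[_model]`.
#' @return Invisibly, the sidecar path.
#' @export
write_image_volume <- function(img, dir, name = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(name))
    name <- paste0(img$source_config_id, "_", img$provenance,
                   if (!is.null(img$model_id)) paste0("_", img$model_id) else "")
  base <- file.path(dir, name)
  RNifti::writeNifti(nifti_with_voxels(img$data, img$voxel_size_mm, "float"),
                     paste0(base, ".nii"))
  side <- list(source_config_id = img$source_config_id,
               provenance = img$provenance, model_id = img$model_id,
               voxel_size_mm = img$voxel_size_mm, dim = dim(img$data),
               total_counts = sum(img$data),
               meta = img$meta[setdiff(names(img$meta), "acq")],
               acq = img$meta$acq)
  write_json_file(side, paste0(base, ".json"))
  invisible(paste0(base, ".json"))
}

#' Read an image volume written by [write_image_volume()]
#' @param path The JSON sidecar path.
#' @return An `image_volume`.
#' @export
read_image_volume <- function(path) {
  side <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- sub("\\.json$", "", path)
  dat <- array(as.numeric(RNifti::readNifti(paste0(base, ".nii"))), side$dim)
  meta <- as.list(side$meta)
  meta$acq <- as.list(side$acq)
  new_image_volume(dat, side$voxel_size_mm, side$provenance,
                   side$source_config_id, model_id = side$model_id,
                   meta = meta)
}

#' Write a patch-pair set (RDS arrays + JSON manifest)
#' @param set A `patch_pair_set`.
#' @param path Output path without extension.
#' @return Invisibly, the manifest path.
#' @export
write_patch_set <- function(set, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(unclass(set), paste0(path, ".rds"))
  write_json_file(list(split = set$split, stride = set$stride,
                       n_patches = dim(set$inputs)[3],
                       patch = dim(set$inputs)[1],
                       label_size = dim(set$labels)[1],
                       normalization = set$normalization),
                  paste0(path, ".json"))
  invisible(paste0(path, ".json"))
}

#' Read a patch-pair set written by [write_patch_set()]
#' @param path Path without extension.
#' @return A `patch_pair_set`.
#' @export
read_patch_set <- function(path) {
  s <- readRDS(paste0(path, ".rds"))
  new_patch_pair_set(s$inputs, s$labels, s$stride, s$split, s$normalization,
                     s$provenance)
}

#' Save a model checkpoint
#'
#' A single RDS archive of the weight tensors plus a JSON description of
#' the architecture, and the training log as CSV.
#'
#' @param model A `trained_model`.
#' @param path Output path without extension.
#' @return Invisibly, the checkpoint path.
#' @export
save_model <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(unclass(model), paste0(path, ".rds"))
  write_json_file(unclass(model$spec), paste0(path, "_spec.json"))
  if (length(model$history)) {
    log <- data.frame(iteration = seq_along(model$history),
                      loss = model$history)
    if (!is.null(model$test_history))
      log <- merge(log, model$test_history, by = "iteration", all.x = TRUE)
    write.csv(log, paste0(path, "_log.csv"), row.names = FALSE)
  }
  invisible(paste0(path, ".rds"))
}

#' Load a model checkpoint saved by [save_model()]
#' @param path Path without extension.
#' @return A `trained_model`.
#' @export
load_model <- function(path) {
  m <- readRDS(paste0(path, ".rds"))
  m$spec <- structure(m$spec, class = "model_spec")
  structure(m, class = "trained_model")
}

#' Write a metrics table as JSON and CSV
#' @param table A tibble from [metrics_table()].
#' @param path Output path without extension.
#' @return Invisibly, the JSON path.
#' @export
write_metrics_report <- function(table, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write_json_file(table, paste0(path, ".json"))
  write.csv(table, paste0(path, ".csv"), row.names = FALSE)
  invisible(paste0(path, ".json"))
}
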