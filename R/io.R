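#' Write a voxel volume as NIfTI
#'
#' Spacing goes into the NIfTI pixdim; the semantics tag is stored in a JSON
#' sidecar next to the image.
#'
#' @param vol a [voxel_volume()].
#' @param path output path (`.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values, pixdim = vol$spacing)
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(semantics = vol$semantics, origin = vol$origin,
                            spacing = vol$spacing),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a voxel volume from NIfTI
#'
#' @param path a `.nii`/`.nii.gz` written by [write_volume()] (the JSON
#'   sidecar, if present, restores semantics and origin).
#' @return a [voxel_volume()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img))
  spacing <- RNifti::pixdim(img)[seq_along(dim(img))]
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  semantics <- "activity"; origin <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    semantics <- meta$semantics; origin <- meta$origin
    spacing <- meta$spacing
  }
  voxel_volume(vals, spacing, origin, semantics)
}

#' Write a PET frame series
#'
#' Sinogram frames as one NIfTI stack (bins x angles x frames) plus
#' `frames.csv` (start, duration, counts) and a JSON sidecar with
#' calibration and background.
#'
#' @param frames a [acquire_pet()] series.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_frame_series <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  arr <- array(frames$counts, c(frames$n_bins, frames$n_angles,
                                ncol(frames$counts)))
  RNifti::writeNifti(RNifti::asNifti(arr), file.path(dir, "frames.nii.gz"))
  utils::write.csv(data.frame(start = frames$t_start,
                              duration = frames$frame_dur,
                              counts = colSums(frames$counts)),
                   file.path(dir, "frames.csv"), row.names = FALSE)
  jsonlite::write_json(list(calib = frames$calib, bg_rate = frames$bg_rate,
                            duration = frames$duration, noise = frames$noise,
                            n_bins = frames$n_bins,
                            n_angles = frames$n_angles),
                       file.path(dir, "frames.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Write a surrogate series as CSV
#' @param surrogate a [extract_surrogate()] series.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_surrogate <- function(surrogate, path) {
  utils::write.csv(as.data.frame(surrogate), path, row.names = FALSE)
  invisible(path)
}

#' Persist a motion model
#'
#' Coefficients as one multi-channel NIfTI (x/y component by c0/c1/c2) plus
#' JSON metadata (reference state, surrogate range, diagnostics summary).
#'
#' @param model a `motion_model`.
#' @param prefix output path prefix; writes `<prefix>.nii.gz` and
#'   `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
write_motion_model <- function(model, prefix) {
  dims <- dim(model$c0)[1:2]
  arr <- array(0, c(dims, 2L, 3L))
  arr[, , , 1] <- model$c0; arr[, , , 2] <- model$c1; arr[, , , 3] <- model$c2
  RNifti::writeNifti(RNifti::asNifti(arr), paste0(prefix, ".nii.gz"))
  jsonlite::write_json(list(spacing = model$spacing,
                            ref_state = as.list(model$ref_state),
                            s_range = model$s_range,
                            n_used = model$diagnostics$n_used,
                            robust = model$diagnostics$robust),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a motion model written by [write_motion_model()]
#' @param prefix path prefix used when writing.
#' @return a `motion_model`.
#' @export
read_motion_model <- function(prefix) {
  arr <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  dims <- dim(arr)[1:2]
  get3 <- function(k) array(arr[, , , k], c(dims, 2L))
  new_motion_model(get3(1), get3(2), get3(3), meta$spacing,
                   ref_state = unlist(meta$ref_state),
                   s_range = meta$s_range,
                   diagnostics = list(robust = meta$robust,
                                      n_used = meta$n_used))
}
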