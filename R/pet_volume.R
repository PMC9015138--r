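#' Construct a PET volume
#'
#' A `pet_volume` is the basic container of the pipeline: a 3-D array of
#' non-negative voxel values, either activity concentration in Bq/ml or
#' standardized uptake values (SUV), with voxel spacing in mm and the
#' acquisition metadata needed for SUV conversion. The z axis is
#' cranio-caudal: slice 1 is the most cranial, z increases caudally.
#'
#' Activity values are assumed to be decay-corrected to injection time, as is
#' standard for reconstructed clinical PET; no decay correction is applied
#' here.
#'
#' @param voxels 3-D numeric array of non-negative, finite values.
#' @param spacing numeric length-3, voxel spacing `(dx, dy, dz)` in mm.
#' @param units `"activity"` (Bq/ml) or `"suv"`.
#' @param dose injected dose in Bq (required to convert activity to SUV).
#' @param weight body weight in kg (required to convert activity to SUV).
#' @param patient_id optional identifier carried through the pipeline.
#' @return An object of class `pet_volume`.
#' @export
pet_volume <- function(voxels, spacing = c(4, 4, 4),
                       units = c("suv", "activity"),
                       dose = NA_real_, weight = NA_real_,
                       patient_id = NA_character_) {
  units <- match.arg(units)
  if (length(dim(voxels)) != 3L)
    stopf("voxels must be a 3-D array, got %d dims", length(dim(voxels)))
  if (!is.numeric(voxels))
    stopf("voxels must be numeric")
  if (anyNA(voxels) || any(!is.finite(voxels)))
    stopf("voxels contain non-finite values")
  if (any(voxels < 0))
    stopf("voxels must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 positive numbers (mm)")
  structure(
    list(voxels = voxels, spacing = spacing, units = units,
         dose = dose, weight = weight, patient_id = patient_id),
    class = "pet_volume"
  )
}

#' @export
print.pet_volume <- function(x, ...) {
  dm <- dim(x$voxels)
  cat(sprintf("<pet_volume> %d x %d x %d voxels, spacing %.1f x %.1f x %.1f mm, units = %s\n",
              dm[1], dm[2], dm[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$units))
  cat(sprintf("  value range [%.3g, %.3g]", min(x$voxels), max(x$voxels)))
  if (!is.na(x$patient_id)) cat(sprintf(", patient %s", x$patient_id))
  cat("\n")
  invisible(x)
}

is_pet_volume <- function(x) inherits(x, "pet_volume")

assert_pet_volume <- function(x) {
  if (!is_pet_volume(x)) stopf("expected a pet_volume object")
  invisible(x)
}

#' Voxel volume in ml
#'
#' @param vol a [pet_volume()] or a numeric length-3 spacing in mm.
#' @return Scalar: the volume of one voxel in ml (1 ml = 1000 mm^3).
#' @export
voxel_volume_ml <- function(vol) {
  sp <- if (is_pet_volume(vol)) vol$spacing else as.numeric(vol)
  prod(sp) / 1000
}

#' Read a PET volume from NIfTI
#'
#' Reads a `.nii`/`.nii.gz` file; voxel spacing is taken from the header.
#' When the voxel values are activity concentration, injected dose and body
#' weight can be supplied directly or through a sidecar key-value text file
#' (`key: value` lines with keys `dose_bq` and `weight_kg`).
#'
#' @param path NIfTI file path.
#' @param units `"suv"` or `"activity"`.
#' @param dose,weight metadata overriding the sidecar.
#' @param sidecar optional path to a key-value metadata file.
#' @param patient_id identifier; defaults to the file name stem.
#' @return A [pet_volume()].
#' @export
read_pet_nifti <- function(path, units = c("suv", "activity"),
                           dose = NA_real_, weight = NA_real_,
                           sidecar = NULL, patient_id = NULL) {
  units <- match.arg(units)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (!is.null(sidecar)) {
    kv <- read_sidecar(sidecar)
    if (is.na(dose)) dose <- as.numeric(kv[["dose_bq"]] %||% NA)
    if (is.na(weight)) weight <- as.numeric(kv[["weight_kg"]] %||% NA)
  }
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  pet_volume(arr, spacing = sp, units = units,
             dose = dose, weight = weight, patient_id = patient_id)
}

read_sidecar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":", fixed = TRUE)
  out <- lapply(kv, function(p) trimws(paste(p[-1], collapse = ":")))
  names(out) <- trimws(vapply(kv, `[[`, "", 1))
  out
}

#' Write a PET volume (or label map) to NIfTI
#'
#' @param vol a [pet_volume()] or a 3-D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing spacing in mm when `vol` is a bare array.
#' @return `path`, invisibly.
#' @export
write_pet_nifti <- function(vol, path, spacing = c(4, 4, 4)) {
  if (is_pet_volume(vol)) {
    arr <- vol$voxels
    spacing <- vol$spacing
  } else arr <- vol
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
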