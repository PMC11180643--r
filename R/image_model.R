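# Domain types: 3-D image volumes, binary ROI masks, paired patient records.
#
# Conventions: arrays are indexed (i, j, k) with i the fastest-varying axis;
# spacing and origin follow the same axis order; the world coordinate of voxel
# (i, j, k) (0-based) is origin + (i, j, k) * spacing (identity orientation).

GEOM_TOL <- 1e-6

#' Construct an image volume
#'
#' A 3-D scalar grid with physical spacing (mm per voxel along each index
#' axis), origin (mm) and a modality tag (intensities are HU for CT,
#' arbitrary units for MRI).
#'
#' @param data 3-D numeric array with all extents >= 1.
#' @param spacing Positive length-3 numeric, mm.
#' @param origin Length-3 numeric, mm. Default c(0, 0, 0).
#' @param modality "CT" or "MRI".
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0), modality = c("CT", "MRI")) {
  modality <- match.arg(modality)
  if (length(dim(data)) != 3L) stop("data must have exactly 3 axes")
  if (any(dim(data) < 1L)) stop("each axis must have extent >= 1")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values")
  if (any(!is.finite(data))) stop("non-finite voxel values")
  structure(list(data = data, spacing = as.double(spacing),
                 origin = as.double(origin), modality = modality),
            class = "image_volume")
}

#' Construct a binary ROI mask
#'
#' A binary 3-D grid aligned to an image volume; any nonzero input value is
#' foreground. Masks define the voxels entering feature computation.
#'
#' @param data 3-D array; nonzero = foreground.
#' @param spacing,origin Grid geometry, as [image_volume()].
#' @return An object of class `roi_mask` with 0/1 integer data.
#' @export
roi_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("data must have exactly 3 axes")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive finite values")
  bin <- array(as.integer(data != 0), dim = dim(data))
  structure(list(data = bin, spacing = as.double(spacing),
                 origin = as.double(origin)),
            class = "roi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s %s, spacing %s mm, range [%.4g, %.4g]>\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask %s, %d foreground voxels>\n",
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

#' Paired CT/MRI patient record
#'
#' Bundles one patient's CT and MRI volume/mask pairs. Both modality pairs
#' must be present and each mask must sit on its volume's grid.
#'
#' @param patient_id Character scalar.
#' @param ct,mri Lists `list(volume = image_volume, mask = roi_mask)`.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, ct, mri) {
  for (side in list(ct, mri)) {
    stopifnot(inherits(side$volume, "image_volume"), inherits(side$mask, "roi_mask"))
    check_same_grid(side$mask, side$volume)
  }
  if (ct$volume$modality != "CT") stop("ct$volume must have modality CT")
  if (mri$volume$modality != "MRI") stop("mri$volume must have modality MRI")
  structure(list(patient_id = as.character(patient_id), ct = ct, mri = mri),
            class = "patient_record")
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("grid mismatch: shape ", paste(dim(a$data), collapse = "x"),
         " vs ", paste(dim(b$data), collapse = "x"))
  if (any(abs(a$spacing - b$spacing) > GEOM_TOL))
    stop("grid mismatch: spacing (", paste(format(a$spacing), collapse = ", "),
         ") vs (", paste(format(b$spacing), collapse = ", "), ")")
  if (any(abs(a$origin - b$origin) > GEOM_TOL))
    stop("grid mismatch: origin (", paste(format(a$origin), collapse = ", "),
         ") vs (", paste(format(b$origin), collapse = ", "), ")")
  invisible(TRUE)
}

#' Read a volume from a NIfTI-1 file
#'
#' @param path `.nii` or `.nii.gz` file with a 3-D image.
#' @param modality Modality tag to attach ("CT" or "MRI").
#' @return An [image_volume()].
#' @export
read_volume <- function(path, modality = c("CT", "MRI")) {
  modality <- match.arg(modality)
  raw <- read_nifti(path)
  image_volume(raw$data, raw$spacing, raw$origin, modality)
}

#' Read an ROI mask and check it against a reference volume
#'
#' Any nonzero label is foreground. The mask grid must match the reference
#' grid (shape exactly, spacing/origin within 1e-6 mm).
#'
#' @param path NIfTI-1 mask file.
#' @param reference The [image_volume()] the mask belongs to.
#' @return An [roi_mask()].
#' @export
read_mask <- function(path, reference) {
  stopifnot(inherits(reference, "image_volume"))
  raw <- read_nifti(path)
  m <- roi_mask(raw$data, raw$spacing, raw$origin)
  check_same_grid(m, reference)
  m
}

#' Write a volume or mask to NIfTI-1
#'
#' Volumes are stored as float64 (bit-exact round trip); masks as uint8.
#'
#' @param vol An [image_volume()] or [roi_mask()].
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "roi_mask")) {
    write_nifti(vol$data, vol$spacing, vol$origin, path, datatype = "uint8")
  } else if (inherits(vol, "image_volume")) {
    write_nifti(vol$data, vol$spacing, vol$origin, path, datatype = "float64")
  } else stop("vol must be an image_volume or roi_mask")
  invisible(path)
}

mask_count <- function(mask) sum(mask$data)

voxel_centers_mm <- function(dims, spacing, origin) {
  # world coordinates of all voxel centers, as a 3-column matrix (x fastest)
  gx <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  gy <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  gz <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  cbind(rep(gx, times = dims[2] * dims[3]),
        rep(rep(gy, each = dims[1]), times = dims[3]),
        rep(gz, each = dims[1] * dims[2]))
}
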