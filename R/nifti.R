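# Minimal NIfTI-1 I/O.
#
# No NIfTI reader ships with the supported R stack, so the small subset of the
# format this package needs is implemented here: single-file .nii / .nii.gz,
# little-endian, 3-D images, datatypes uint8 / int16 / int32 / float32 /
# float64, axis-aligned orientation (identity up to axis flips). Anything else
# is rejected with a diagnostic rather than silently reinterpreted.

NIFTI_DT <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L)
)

nifti_con <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

raw_i <- function(buf, off, n, size, signed = TRUE) {
  readBin(buf[(off + 1):(off + n * size)], "integer",
          n = n, size = size, signed = signed, endian = "little")
}

raw_f <- function(buf, off, n, size = 4L) {
  readBin(buf[(off + 1):(off + n * size)], "double",
          n = n, size = size, endian = "little")
}

#' Read a 3-D NIfTI-1 image
#'
#' Reads a single-file NIfTI-1 volume (`.nii` or `.nii.gz`), applies the
#' header's `scl_slope`/`scl_inter` intensity scaling, and returns the raw
#' array plus grid geometry. Only axis-aligned orientations (identity up to
#' flips) are accepted; oblique images are rejected so that no silent
#' reorientation can occur between resampling and shape computation.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with `data` (3-D numeric array, x fastest), `spacing` and
#'   `origin` (mm, length-3).
#' @keywords internal
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- nifti_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header: ", path)
  sizeof_hdr <- raw_i(hdr, 0, 1, 4)
  if (sizeof_hdr != 348L)
    stop("not a little-endian NIfTI-1 file (sizeof_hdr = ", sizeof_hdr, "): ", path)
  magic <- rawToChar(hdr[345:347])
  if (!identical(magic, "n+1"))
    stop("unsupported NIfTI magic '", magic, "' (need single-file 'n+1'): ", path)

  dim8 <- raw_i(hdr, 40, 8, 2)
  ndim <- dim8[1]
  if (ndim != 3L) stop("non-3-D image (ndim = ", ndim, "): ", path)
  dims <- dim8[2:4]
  if (any(dims < 1L)) stop("invalid image dimensions: ", paste(dims, collapse = "x"))

  datatype <- raw_i(hdr, 70, 1, 2)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype, ": ", path)

  pixdim <- raw_f(hdr, 76, 8)
  vox_offset <- raw_f(hdr, 108, 1)
  scl_slope <- raw_f(hdr, 112, 1)
  scl_inter <- raw_f(hdr, 116, 1)
  qform_code <- raw_i(hdr, 252, 1, 2)
  sform_code <- raw_i(hdr, 254, 1, 2)

  spacing <- abs(pixdim[2:4])
  origin <- c(0, 0, 0)
  if (sform_code > 0L) {
    srow <- matrix(raw_f(hdr, 280, 12), nrow = 3, byrow = TRUE)
    rot <- srow[, 1:3]
    offd <- rot; diag(offd) <- 0
    if (any(abs(offd) > 1e-4 * max(abs(rot), 1)))
      stop("oblique orientation not supported (non-axis-aligned sform): ", path)
    spacing <- abs(diag(rot))
    origin <- srow[, 4]
  } else if (qform_code > 0L) {
    quat <- raw_f(hdr, 256, 6)
    if (any(abs(quat[1:3]) > 1e-4))
      stop("oblique orientation not supported (rotated qform): ", path)
    origin <- quat[4:6]
  }
  if (any(spacing <= 0)) stop("non-positive voxel spacing in header: ", path)

  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(dims)
  data <- readBin(con, dt$what, n = n, size = dt$size,
                  signed = dt$signed, endian = "little")
  if (length(data) < n) stop("truncated NIfTI data section: ", path)
  data <- as.double(data)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  if (any(!is.finite(data))) stop("non-finite voxel values in: ", path)
  list(data = array(data, dim = dims), spacing = spacing, origin = origin)
}

put_i32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
put_i16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
put_f32 <- function(x) writeBin(as.double(x), raw(), size = 4L, endian = "little")
put_chr <- function(s, n) {
  r <- raw(n)
  b <- charToRaw(s)
  if (length(b) > 0) r[seq_along(b[seq_len(min(length(b), n))])] <- b[seq_len(min(length(b), n))]
  r
}

#' Write a 3-D array as NIfTI-1
#'
#' Writes a single-file NIfTI-1 image with an axis-aligned sform carrying the
#' spacing and origin. `datatype` "float64" round-trips intensities
#' bit-exactly; "uint8" is used for binary masks.
#'
#' @keywords internal
write_nifti <- function(data, spacing, origin, path, datatype = "float64") {
  stopifnot(length(dim(data)) == 3L, all(spacing > 0))
  code <- switch(datatype, uint8 = 2L, float64 = 64L,
                 stop("unsupported write datatype: ", datatype))
  dt <- NIFTI_DT[[as.character(code)]]
  dims <- dim(data)
  hdr <- c(
    put_i32(348L),
    raw(36L),                                     # data_type..dim_info
    put_i16(c(3L, dims, 1L, 1L, 1L, 1L)),         # dim[8]
    put_f32(c(0, 0, 0)), put_i16(0L),             # intent
    put_i16(code), put_i16(dt$bitpix), put_i16(0L),
    put_f32(c(1, spacing, 0, 0, 0, 0)),           # pixdim[8], qfac = 1
    put_f32(352), put_f32(1), put_f32(0),         # vox_offset, scl
    put_i16(0L), raw(1L), as.raw(2L),             # slice_end/code, units = mm
    put_f32(c(0, 0, 0, 0)), put_i32(c(0L, 0L)),
    put_chr("radagree", 80L), raw(24L),
    put_i16(0L), put_i16(1L),                     # qform = 0, sform = 1
    put_f32(rep(0, 6)),
    put_f32(c(spacing[1], 0, 0, origin[1],
              0, spacing[2], 0, origin[2],
              0, 0, spacing[3], origin[3])),
    raw(16L),
    c(charToRaw("n+1"), raw(1L))
  )
  stopifnot(length(hdr) == 348L)
  con <- tryCatch(nifti_con(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path, " (", conditionMessage(e), ")"),
                  warning = function(w) stop("cannot open for writing: ", path, " (", conditionMessage(w), ")"))
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con)                          # no extensions
  if (datatype == "uint8") {
    writeBin(as.raw(as.integer(data)), con)
  } else {
    writeBin(as.double(data), con, size = 8L, endian = "little")
  }
  invisible(path)
}
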