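# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
#
# The offline toolchain ships no NIfTI package for R, so the format is read
# and written directly.  Scope: 3-D volumes, datatypes uint8/int8/int16/
# uint16/int32/float32/float64, scl_slope/scl_inter scaling, sform (preferred)
# or qform affine.  The affine returned maps 0-based voxel indices to world
# mm, matching the package convention.

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param label if `TRUE` return a [label_volume()] (integer codes), else a
#'   [volume3d()].
#' @return A `Volume3D` or `LabelVolume`; spacing and affine come from the
#'   header (sform if set, else qform, else pixdim).
#' @export
read_nifti <- function(path, label = FALSE) {
  if (!file.exists(path)) stop(sprintf("NIfTI file not found: %s", path))
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop(sprintf("truncated NIfTI header: %s", path))
  rb <- function(off, what, n, size, signed = TRUE, endian = "little") {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            signed = signed, endian = endian)
  }
  endi <- "little"
  if (rb(0, "integer", 1, 4) != 348L) {
    endi <- "big"
    if (rb(0, "integer", 1, 4, endian = "big") != 348L)
      stop(sprintf("not a NIfTI-1 file (bad sizeof_hdr): %s", path))
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop(sprintf("unsupported NIfTI magic '%s' in %s", magic, path))
  if (magic == "ni1") stop("two-file (.hdr/.img) NIfTI is not supported")
  dim0 <- rb(40, "integer", 8, 2, endian = endi)
  ndim <- dim0[1]
  if (ndim < 3L || any(dim0[5:8] > 1L))
    stop("only 3-D NIfTI volumes are supported")
  d <- dim0[2:4]
  datatype <- rb(70, "integer", 1, 2, endian = endi)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop(sprintf("unsupported NIfTI datatype code %d", datatype))
  pixdim <- rb(76, "double", 8, 4, endian = endi)
  vox_offset <- rb(108, "double", 1, 4, endian = endi)
  scl_slope <- rb(112, "double", 1, 4, endian = endi)
  scl_inter <- rb(116, "double", 1, 4, endian = endi)
  qform_code <- rb(252, "integer", 1, 2, endian = endi)
  sform_code <- rb(254, "integer", 1, 2, endian = endi)
  quat <- rb(256, "double", 6, 4, endian = endi)
  srow <- matrix(rb(280, "double", 12, 4, endian = endi), nrow = 3, byrow = TRUE)

  spacing <- abs(pixdim[2:4])
  if (any(spacing <= 0)) spacing[spacing <= 0] <- 1
  if (sform_code > 0) {
    affine <- rbind(srow, c(0, 0, 0, 1))
  } else if (qform_code > 0) {
    affine <- qform_to_affine(quat, spacing, qfac = ifelse(pixdim[1] < 0, -1, 1))
  } else {
    affine <- diag(c(spacing, 1))
  }

  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(d)
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = endi)
  if (length(vals) < n) stop(sprintf("truncated NIfTI data in %s", path))
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  arr <- array(as.numeric(vals), dim = d)
  if (label)
    label_volume(array(as.integer(round(arr)), dim = d), spacing, affine)
  else
    volume3d(arr, spacing, affine)
}

qform_to_affine <- function(quat, spacing, qfac = 1) {
  b <- quat[1]; c_ <- quat[2]; d <- quat[3]
  a2 <- 1 - b * b - c_ * c_ - d * d
  a <- if (a2 > 0) sqrt(a2) else 0
  R <- matrix(c(
    a * a + b * b - c_ * c_ - d * d, 2 * (b * c_ - a * d), 2 * (b * d + a * c_),
    2 * (b * c_ + a * d), a * a + c_ * c_ - b * b - d * d, 2 * (c_ * d - a * b),
    2 * (b * d - a * c_), 2 * (c_ * d + a * b), a * a + d * d - b * b - c_ * c_),
    nrow = 3, byrow = TRUE)
  S <- diag(c(spacing[1], spacing[2], spacing[3] * qfac))
  rbind(cbind(R %*% S, quat[4:6]), c(0, 0, 0, 1))
}

#' Write a volume as NIfTI-1
#'
#' Scalar volumes are written as float32, label volumes as int16.  The affine
#' is stored in the sform (code 2); gzip compression is chosen by a `.gz`
#' suffix.
#'
#' @param vol a `Volume3D` or `LabelVolume`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  if (!inherits(vol, c("Volume3D", "LabelVolume")))
    stop("vol must be a Volume3D or LabelVolume")
  arr <- vol_data(vol)
  is_lab <- inherits(vol, "LabelVolume")
  datatype <- if (is_lab) 4L else 16L
  bitpix <- if (is_lab) 16L else 32L
  d <- dim(arr)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size = NA_integer_) {
    if (is.character(x)) {
      writeBin(charToRaw(x), con)
    } else writeBin(x, con, size = size, endian = "little")
  }
  pad <- function(n) writeBin(raw(n), con)
  wb(348L, 4L)                                 # sizeof_hdr
  pad(35); wb(as.integer(charToRaw("r")), 1L)  # data_type/db_name/extents etc.
  wb(c(3L, d, 1L, 1L, 1L, 1L), 2L)             # dim[8]
  pad(14)                                      # intent params/codes
  wb(datatype, 2L); wb(bitpix, 2L); wb(0L, 2L) # datatype, bitpix, slice_start
  wb(c(1, vol$spacing, 0, 0, 0, 0), 4L)        # pixdim[8], qfac = 1
  wb(352, 4L)                                  # vox_offset
  wb(c(1, 0), 4L)                              # scl_slope, scl_inter
  pad(3)                                       # slice_end, slice_code
  wb(10L, 1L)                                  # xyzt_units: mm | sec
  wb(c(0, 0, 0), 4L)                           # cal_max, cal_min, slice_dur
  wb(0, 4L)                                    # toffset
  pad(8)                                       # glmax, glmin
  pad(80 + 24)                                 # descrip, aux_file
  wb(c(0L, 2L), 2L)                            # qform_code = 0, sform_code = 2
  wb(rep(0, 6), 4L)                            # quaternion/offsets
  wb(as.numeric(t(vol$affine[1:3, ])), 4L)     # srow_x/y/z
  pad(16)                                      # intent_name
  wb("n+1"); pad(1)                            # magic
  pad(4)                                       # extension flag
  if (is_lab) {
    if (any(arr < -32768 | arr > 32767)) stop("label codes exceed int16 range")
    wb(as.integer(arr), 2L)
  } else {
    wb(as.numeric(arr), 4L)
  }
  invisible(path)
}
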