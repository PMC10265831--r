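# Minimal NIfTI-1 reader/writer.
#
# Only the subset of the format this pipeline touches is supported: single-file
# .nii / .nii.gz, 3D or 4D, datatypes uint8/int16/int32/float32/float64, no
# extensions, scl_slope/scl_inter applied when present. Written files are
# little-endian with vox_offset 352.

NIFTI_TYPES <- list(
  `2`  = list(what = "integer", size = 1, signed = FALSE, mode = "int"),
  `4`  = list(what = "integer", size = 2, signed = TRUE,  mode = "int"),
  `8`  = list(what = "integer", size = 4, signed = TRUE,  mode = "int"),
  `16` = list(what = "double",  size = 4, signed = TRUE,  mode = "dbl"),
  `64` = list(what = "double",  size = 8, signed = TRUE,  mode = "dbl")
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 image
#'
#' Reads a single-file NIfTI-1 volume (`.nii` or `.nii.gz`) into an array.
#' Supports 3D and 4D images with datatypes uint8, int16, int32, float32 and
#' float64; both byte orders are handled.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A numeric array with attributes `pixdim` (voxel edge lengths for
#'   the spatial dimensions, mm) and `datatype` (NIfTI datatype code).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1, 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    if (bitwAnd(bitwShiftR(sizeof_hdr, 24), 255L) != 92L) {
      # 348 byte-swapped is 0x5C010000; quick sanity check
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
    }
  }
  readBin(con, "raw", 36)                                   # unused fields
  dim <- readBin(con, "integer", 8, 2, endian = endian)     # dim[0..7]
  readBin(con, "raw", 14)                                   # intent fields
  datatype <- readBin(con, "integer", 1, 2, endian = endian)
  readBin(con, "integer", 1, 2, endian = endian)            # bitpix
  readBin(con, "integer", 1, 2, endian = endian)            # slice_start
  pixdim <- readBin(con, "double", 8, 4, endian = endian)
  vox_offset <- readBin(con, "double", 1, 4, endian = endian)
  scl_slope <- readBin(con, "double", 1, 4, endian = endian)
  scl_inter <- readBin(con, "double", 1, 4, endian = endian)
  # skip remainder of header up to vox_offset
  readBin(con, "raw", 348 - 132)
  magic_block <- readBin(con, "raw", max(0, round(vox_offset) - 348))
  ndim <- dim[1]
  if (!ndim %in% c(2L, 3L, 4L)) stop("unsupported image dimensionality: ", ndim)
  shape <- dim[2:(1 + ndim)]
  typ <- NIFTI_TYPES[[as.character(datatype)]]
  if (is.null(typ)) stop("unsupported NIfTI datatype code: ", datatype)
  n <- prod(shape)
  vals <- readBin(con, typ$what, n, typ$size, signed = typ$signed,
                  endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  img <- array(vals, dim = shape)
  attr(img, "pixdim") <- pixdim[2:(1 + min(ndim, 3))]
  attr(img, "datatype") <- datatype
  img
}

#' Write a NIfTI-1 image
#'
#' Writes a 3D or 4D array as a little-endian single-file NIfTI-1 volume.
#'
#' @param img Numeric or integer array, 3D or 4D.
#' @param path Output path; a `.gz` suffix selects gzip compression.
#' @param pixdim Voxel edge lengths (mm) for the spatial dimensions.
#' @param datatype NIfTI datatype code: 8 (int32) or 64 (float64).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, pixdim = c(1, 1, 1), datatype = 64L) {
  shape <- dim(img)
  ndim <- length(shape)
  if (!ndim %in% c(3L, 4L)) stop("only 3D/4D images are written")
  if (!datatype %in% c(8L, 64L)) stop("supported write datatypes: 8, 64")
  bitpix <- if (datatype == 8L) 32L else 64L
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, 4, endian = "little")
  writeBin(raw(36), con)
  dimv <- integer(8); dimv[1] <- ndim; dimv[2:(1 + ndim)] <- shape
  dimv[(2 + ndim):8] <- 1L
  writeBin(as.integer(dimv), con, 2, endian = "little")
  writeBin(raw(14), con)
  writeBin(as.integer(datatype), con, 2, endian = "little")
  writeBin(as.integer(bitpix), con, 2, endian = "little")
  writeBin(0L, con, 2, endian = "little")
  pd <- numeric(8); pd[1] <- 1
  pd[2:(1 + min(ndim, 3))] <- pixdim[seq_len(min(ndim, 3))]
  if (ndim == 4L) pd[5] <- 1
  writeBin(pd, con, 4, endian = "little")
  writeBin(352, con, 4, endian = "little")   # vox_offset
  writeBin(c(1, 0), con, 4, endian = "little")  # scl_slope, scl_inter
  # pad header bytes 132..348, then the 4-byte gap before data; embed magic
  pad <- raw(348 - 132)
  magic <- charToRaw("n+1")
  pad[(344 - 132 + 1):(344 - 132 + 3)] <- magic   # magic at offset 344
  writeBin(pad, con)
  writeBin(raw(4), con)
  if (datatype == 8L) {
    writeBin(as.integer(round(img)), con, 4, endian = "little")
  } else {
    writeBin(as.double(img), con, 8, endian = "little")
  }
  invisible(path)
}
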