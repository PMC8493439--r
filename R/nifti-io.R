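# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
# Only the fields the pipeline needs are honoured: dim, datatype, pixdim,
# scl_slope/scl_inter. World (qform/sform) coordinates are ignored by design:
# the lobar atlas is assumed pre-aligned, and only voxel dimensions enter the
# cm^3 conversion.

.nifti_dtypes <- data.frame(
  code   = c(2L, 4L, 8L, 16L, 64L),
  what   = c("integer", "integer", "integer", "numeric", "numeric"),
  size   = c(1L, 2L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE),
  name   = c("uint8", "int16", "int32", "float32", "float64"),
  stringsAsFactors = FALSE
)

.nifti_con <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`) into an array,
#' applying any `scl_slope`/`scl_inter` rescaling. Both endiannesses are
#' handled. Only scalar datatypes uint8, int16, int32, float32 and float64
#' are supported.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (numeric array, up to 3-D),
#'   `voxdim` (numeric vector of voxel sizes in mm, one per dimension) and
#'   `datatype` (the NIfTI datatype name).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- .nifti_con(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    if (.swap_int32(sizeof_hdr) != 348L)
      stop("malformed NIfTI header (sizeof_hdr != 348): ", path)
  }
  readBin(con, "raw", 36)                                   # unused fields
  dim <- readBin(con, "integer", 8, size = 2, endian = endian)
  readBin(con, "numeric", 3, size = 4, endian = endian)     # intent_p1..3
  readBin(con, "integer", 1, size = 2, endian = endian)     # intent_code
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  readBin(con, "integer", 2, size = 2, endian = endian)     # bitpix, slice_start
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "numeric", 1, size = 4, endian = endian)
  readBin(con, "raw", 348 - 120)
  nd <- dim[1]
  if (nd < 1 || nd > 7) stop("malformed NIfTI header (dim[0] = ", nd, ")")
  shape <- dim[2:(nd + 1)]
  spec <- .nifti_dtypes[.nifti_dtypes$code == datatype, ]
  if (nrow(spec) != 1)
    stop("unsupported NIfTI datatype code: ", datatype)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(shape)
  vals <- readBin(con, spec$what, n, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) != n) stop("truncated NIfTI data section: ", path)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  if (anyNA(vals)) stop("non-finite values in NIfTI volume: ", path)
  list(data = array(vals, dim = shape),
       voxdim = abs(pixdim[2:(nd + 1)]),
       datatype = spec$name)
}

.swap_int32 <- function(x) {
  r <- writeBin(as.integer(x), raw(), size = 4, endian = "little")
  readBin(r, "integer", 1, size = 4, endian = "big")
}

#' Write a NIfTI-1 volume
#'
#' Writes an array as a little-endian single-file NIfTI-1 image. The path's
#' extension decides gzip compression (`.nii.gz` vs `.nii`).
#'
#' @param data Numeric, integer or logical array (1-D to 3-D).
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param voxdim Voxel dimensions in mm, recycled to the array rank.
#' @param datatype One of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, voxdim = 1, datatype = "float32") {
  spec <- .nifti_dtypes[.nifti_dtypes$name == datatype, ]
  if (nrow(spec) != 1)
    stop("unsupported datatype: ", datatype)
  if (is.logical(data)) data <- array(as.integer(data), dim = dim(data) %||% length(data))
  shape <- dim(data) %||% length(data)
  nd <- length(shape)
  if (nd > 3) stop("only volumes up to 3-D are written")
  vals <- as.vector(data)
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("refusing to write non-finite values")
  voxdim <- rep_len(as.numeric(voxdim), nd)
  if (any(voxdim <= 0)) stop("voxel dimensions must be positive")

  dim8 <- integer(8); dim8[1] <- nd; dim8[2:(nd + 1)] <- shape
  dim8[dim8 == 0L] <- 1L; dim8[1] <- nd
  pixdim8 <- numeric(8); pixdim8[2:(nd + 1)] <- voxdim

  con <- .nifti_con(path, "wb")
  on.exit(close(con))
  wint <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wint(348L, 4)                       # sizeof_hdr
  writeBin(raw(36), con)              # data_type..dim_info
  wint(dim8, 2)
  wflt(c(0, 0, 0))                    # intent_p1..3
  wint(0L, 2)                         # intent_code
  wint(spec$code, 2)                  # datatype
  wint(spec$size * 8L, 2)             # bitpix
  wint(0L, 2)                         # slice_start
  wflt(pixdim8)
  wflt(352)                           # vox_offset
  wflt(c(1, 0))                       # scl_slope, scl_inter
  wint(0L, 2)                         # slice_end
  writeBin(raw(2), con)               # slice_code, xyzt_units
  wflt(c(0, 0, 0, 0))                 # cal_max..toffset
  wint(c(0L, 0L), 4)                  # glmax, glmin
  writeBin(raw(80 + 24), con)         # descrip, aux_file
  wint(c(0L, 0L), 2)                  # qform_code, sform_code
  wflt(numeric(6))                    # quaternion + offsets
  srow <- rbind(c(voxdim[1], 0, 0, 0),
                c(0, rep_len(voxdim, 3)[2], 0, 0),
                c(0, 0, rep_len(voxdim, 3)[3], 0))
  wflt(t(srow))                       # srow_x/y/z (informational only)
  writeBin(raw(16), con)              # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)
  writeBin(raw(4), con)               # extender
  if (spec$what == "integer") {
    iv <- as.integer(round(vals))
    if (datatype == "int16" && any(abs(iv) > 32767))
      stop("values exceed int16 range")
    if (datatype == "uint8" && (any(iv < 0) || any(iv > 255)))
      stop("values exceed uint8 range")
    writeBin(iv, con, size = spec$size, endian = "little")
  } else {
    writeBin(vals, con, size = spec$size, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
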