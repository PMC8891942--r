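#' Minimal NIfTI-1 volume input/output
#'
#' `read_nifti()` and `write_nifti()` implement the subset of the NIfTI-1
#' standard this package needs: single-file (`.nii`, optionally gzipped
#' `.nii.gz`) 3D or 3D+time volumes with an sform affine. No R NIfTI reader
#' ships with the supported dependency set, so the 348-byte header is parsed
#' directly. Data types uint8, int16, int32, float32 and float64 are read;
#' `scl_slope`/`scl_inter` rescaling and both endiannesses are honoured.
#' Volumes are always written as float64 with `sform_code = 1`.
#'
#' @param path file path; a `.gz` suffix (or gzip magic bytes on read)
#'   selects transparent compression.
#' @return `read_nifti()` returns a list with elements `data` (numeric array,
#'   3 or 4 dimensions), `affine` (4x4 grid-to-world matrix over 0-based
#'   voxel indices) and `tr` (the 4th-dimension step, seconds; `NA` for 3D).
#' @name nifti_io
NULL

.nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double",  size = 4L, signed = TRUE),
  `64` = list(what = "double",  size = 8L, signed = TRUE)
)

.is_gzipped <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

#' @rdname nifti_io
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- if (.is_gzipped(path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))

  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header in ", path)
  rd <- function(offset, what, n, size, endian, signed = TRUE) {
    rc <- rawConnection(hdr_raw[(offset + 1L):(offset + n * size)])
    on.exit(close(rc), add = TRUE)
    readBin(rc, what, n = n, size = size, endian = endian, signed = signed)
  }
  endian <- "little"
  sizeof_hdr <- rd(0L, "integer", 1L, 4L, endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- rd(0L, "integer", 1L, 4L, endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic): ", path)
  if (magic == "ni1") stop("detached .hdr/.img pairs are not supported: ", path)

  dim_field <- rd(40L, "integer", 8L, 2L, endian)
  ndim <- dim_field[1]
  if (!ndim %in% c(3L, 4L)) stop("only 3D or 4D volumes supported, got ndim = ", ndim)
  dims <- dim_field[2:(1 + ndim)]
  datatype <- rd(70L, "integer", 1L, 2L, endian)
  dt <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  pixdim <- rd(76L, "double", 8L, 4L, endian)
  vox_offset <- rd(108L, "double", 1L, 4L, endian)
  scl_slope <- rd(112L, "double", 1L, 4L, endian)
  scl_inter <- rd(116L, "double", 1L, 4L, endian)
  sform_code <- rd(254L, "integer", 1L, 2L, endian)
  srow <- matrix(rd(280L, "double", 12L, 4L, endian), nrow = 3, byrow = TRUE)

  affine <- diag(4)
  if (sform_code > 0L) {
    affine[1:3, ] <- srow
  } else {
    # fall back to a pixdim-scaled axis-aligned affine (qform ignored)
    affine[1, 1] <- pixdim[2]; affine[2, 2] <- pixdim[3]; affine[3, 3] <- pixdim[4]
  }

  skip <- round(vox_offset) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n_vox <- prod(dims)
  values <- readBin(con, dt$what, n = n_vox, size = dt$size,
                    endian = endian, signed = dt$signed)
  if (length(values) < n_vox) stop("truncated NIfTI data in ", path)
  values <- as.double(values)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    values <- values * scl_slope + scl_inter
  }
  data <- array(values, dim = dims)
  tr <- if (ndim == 4L) pixdim[5] else NA_real_
  list(data = data, affine = affine, tr = tr)
}

#' @rdname nifti_io
#' @param data numeric array with 3 or 4 dimensions.
#' @param affine 4x4 numeric grid-to-world matrix (0-based voxel indices).
#' @param tr sampling interval written to `pixdim[4]` for 4D volumes, seconds.
#' @export
write_nifti <- function(data, affine, path, tr = 1) {
  dims <- dim(data)
  if (is.null(dims) || !length(dims) %in% c(3L, 4L)) {
    stop("`data` must be a 3D or 4D array")
  }
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  voxdim <- sqrt(colSums(affine[1:3, 1:3]^2))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_chr <- function(s, n) {
    r <- raw(n)
    b <- charToRaw(s)
    if (length(b)) r[seq_along(b)] <- b
    writeBin(r, con)
  }

  w_i32(348L)                     # sizeof_hdr
  w_chr("", 10L); w_chr("", 18L)  # data_type, db_name (unused)
  w_i32(0L); w_i16(0L)            # extents, session_error
  w_chr("r", 1L); w_chr("", 1L)   # regular, dim_info
  dimf <- rep(1L, 8L)
  dimf[1] <- length(dims)
  dimf[1 + seq_along(dims)] <- dims
  w_i16(dimf)
  w_f32(c(0, 0, 0)); w_i16(0L)    # intent_p1..3, intent_code
  w_i16(64L); w_i16(64L)          # datatype float64, bitpix
  w_i16(0L)                       # slice_start
  pixdim <- c(1, voxdim, if (length(dims) == 4L) tr else 1, 1, 1, 1)
  w_f32(pixdim)
  w_f32(352)                      # vox_offset
  w_f32(1); w_f32(0)              # scl_slope, scl_inter
  w_i16(0L); w_chr("", 1L)        # slice_end, slice_code
  w_chr(rawToChar(as.raw(10L)), 1L)  # xyzt_units: mm | sec
  w_f32(c(0, 0, 0, 0))            # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                # glmax, glmin
  w_chr("pasym", 80L); w_chr("", 24L)  # descrip, aux_file
  w_i16(0L); w_i16(1L)            # qform_code = 0, sform_code = 1
  w_f32(c(0, 0, 0)); w_f32(c(0, 0, 0))  # quaternions, qoffsets
  w_f32(t(affine[1:3, ]))         # srow_x, srow_y, srow_z
  w_chr("", 16L)
  w_chr("n+1", 4L)
  writeBin(raw(4L), con)          # no header extensions
  writeBin(as.double(data), con, size = 8L, endian = "little")
  invisible(path)
}
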