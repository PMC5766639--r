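# Minimal NIfTI-1 reader/writer. None of the pre-installed R packages
# provide NIfTI support, so the 348-byte single-file (.nii / .nii.gz)
# format is handled directly: float32/float64 output, the common integer
# and float datatypes on input, byte-swapped files detected via
# sizeof_hdr. The affine is limited to a diagonal sform built from the
# voxel size; no resampling or reorientation anywhere.

nifti_datatypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "numeric", size = 4L, signed = TRUE),
  `64`  = list(what = "numeric", size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

pad_string <- function(s, n) {
  raw_s <- charToRaw(substr(s, 1, n - 1))
  c(raw_s, raw(n - length(raw_s)))
}

#' Write an array as a NIfTI-1 file
#'
#' Writes a 3D or 4D numeric array as a single-file NIfTI-1 image
#' (gzip-compressed when the path ends in `.gz`). Data are stored as
#' float32 by default; `NA` values are written as NaN.
#'
#' @param data 3D or 4D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size length-3 voxel dimensions, mm.
#' @param description up to 79 characters stored in the header.
#' @param datatype `"float32"` (default) or `"float64"`.
#' @return Invisibly, `path`.
#' @export
write_nifti <- function(data, path, voxel_size = c(1, 1, 1),
                        description = "", datatype = "float32") {
  data <- as.array(data)
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stop("data must be a 3D or 4D array")
  dt_code <- switch(datatype, float32 = 16L, float64 = 64L,
                    stop("unsupported datatype"))
  bitpix <- if (dt_code == 16L) 32L else 64L
  dims <- integer(8); dims[1] <- nd; dims[1 + seq_len(nd)] <- dim(data)
  dims[dims == 0] <- 1L
  pixdim <- numeric(8)
  pixdim[1] <- 1  # qfac
  pixdim[2:4] <- voxel_size
  pixdim[5] <- 1

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L,
                                endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L,
                                endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L,
                                endian = "little")
  w_raw <- function(x) writeBin(x, con)

  w_i32(348L)                      # sizeof_hdr
  w_raw(raw(10))                   # data_type
  w_raw(raw(18))                   # db_name
  w_i32(0L)                        # extents
  w_i16(0L)                        # session_error
  w_raw(charToRaw("r"))            # regular
  w_raw(raw(1))                    # dim_info
  w_i16(dims)                      # dim[8]
  w_f32(c(0, 0, 0))                # intent_p1..3
  w_i16(0L)                        # intent_code
  w_i16(dt_code)                   # datatype
  w_i16(bitpix)                    # bitpix
  w_i16(0L)                        # slice_start
  w_f32(pixdim)                    # pixdim[8]
  w_f32(352)                       # vox_offset
  w_f32(1)                         # scl_slope
  w_f32(0)                         # scl_inter
  w_i16(0L)                        # slice_end
  w_raw(raw(1))                    # slice_code
  w_raw(as.raw(2L))                # xyzt_units: mm
  w_f32(c(0, 0, 0, 0))             # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                 # glmax, glmin
  w_raw(pad_string(description, 80L))  # descrip
  w_raw(raw(24))                   # aux_file
  w_i16(0L)                        # qform_code
  w_i16(1L)                        # sform_code
  w_f32(c(0, 0, 0))                # quatern_b,c,d
  w_f32(c(0, 0, 0))                # qoffset_x,y,z
  w_f32(c(voxel_size[1], 0, 0, 0)) # srow_x
  w_f32(c(0, voxel_size[2], 0, 0)) # srow_y
  w_f32(c(0, 0, voxel_size[3], 0)) # srow_z
  w_raw(raw(16))                   # intent_name
  w_raw(c(charToRaw("n+1"), raw(1)))  # magic
  w_raw(raw(4))                    # extension flag
  vals <- as.numeric(data)
  vals[is.na(vals)] <- NaN
  writeBin(vals, con, size = bitpix %/% 8L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 file
#'
#' Reads a single-file NIfTI-1 image (optionally gzipped), handling both
#' byte orders and the common datatypes, and applying any scale
#' slope/intercept.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return List: `data` (numeric array), `voxel_size`, `description`,
#'   `datatype` (NIfTI code).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")  # gzfile transparently reads plain files too
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header")
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr)")
  }
  r_i16 <- function(off, n) readBin(hdr[off + seq_len(2L * n)], "integer",
                                    n = n, size = 2L, endian = endian)
  r_f32 <- function(off, n) readBin(hdr[off + seq_len(4L * n)], "numeric",
                                    n = n, size = 4L, endian = endian)
  dims <- r_i16(40L, 8L)
  nd <- dims[1]
  if (nd < 3L || nd > 4L) stop("only 3D or 4D images are supported")
  shape <- dims[1 + seq_len(nd)]
  datatype <- r_i16(70L, 1L)
  pixdim <- r_f32(76L, 8L)
  vox_offset <- r_f32(108L, 1L)
  scl_slope <- r_f32(112L, 1L)
  scl_inter <- r_f32(116L, 1L)
  descrip_raw <- hdr[149:228]
  nz <- which(descrip_raw != 0)
  descrip <- if (length(nz)) rawToChar(descrip_raw[seq_len(max(nz))]) else ""
  spec <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code: ", datatype)
  skip <- vox_offset - 348L
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n <- prod(shape)
  vals <- readBin(con, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data section")
  vals <- as.numeric(vals)
  if (!is.na(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, shape), voxel_size = pixdim[2:4],
       description = descrip, datatype = datatype)
}
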