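# Minimal NIfTI-1 reader/writer.
#
# Scope: single-file .nii / .nii.gz, 3-D and 4-D images, data types
# uint8/int16/int32/float32/float64, sform (srow_*) affine with a pixdim
# fallback.  Integer arrays round-trip bit-exactly; floats to IEEE double
# precision.  This is deliberately not a general NIfTI library: it covers
# the artifacts this pipeline reads and writes.

NIFTI_TYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, mode = "integer"),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  mode = "integer"),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  mode = "integer"),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  mode = "double"),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  mode = "double")
)

nii_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return a [volume_grid].  The affine is taken from the sform rows when
#'   `sform_code > 0`, otherwise a diagonal affine is built from `pixdim`.
#' @export
read_volume <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path,
              class = "bxs_format_error")
  con <- nii_connection(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348L)
  assert_that(length(hdr_raw) == 348L, "truncated NIfTI header in %s", path,
              class = "bxs_format_error")
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
    assert_that(sizeof_hdr == 348L,
                "malformed NIfTI header (sizeof_hdr != 348) in %s", path,
                class = "bxs_format_error")
  }
  rd_i16 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 2L * n)],
                                     "integer", n, 2L, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 4L * n)],
                                     "double", n, 4L, endian = endian)
  magic <- rawToChar(hdr_raw[345:347])
  assert_that(magic %in% c("n+1", "ni1"),
              "malformed NIfTI header (bad magic %s) in %s", magic, path,
              class = "bxs_format_error")
  dim0 <- rd_i16(40L, 8L)
  ndim <- dim0[1]
  assert_that(ndim >= 3L && ndim <= 4L,
              "unsupported NIfTI dimensionality %d in %s (field dim[0])",
              ndim, path, class = "bxs_format_error")
  shape <- dim0[2:(1 + ndim)]
  assert_that(all(shape > 0), "malformed NIfTI header (nonpositive dim) in %s",
              path, class = "bxs_format_error")
  datatype <- rd_i16(70L, 1L)
  tp <- NIFTI_TYPES[[as.character(datatype)]]
  assert_that(!is.null(tp), "unsupported NIfTI datatype code %d in %s",
              datatype, path, class = "bxs_format_error")
  pixdim <- rd_f32(76L, 8L)
  vox_offset <- rd_f32(108L, 1L)
  scl_slope <- rd_f32(112L, 1L)
  scl_inter <- rd_f32(116L, 1L)
  sform_code <- rd_i16(254L, 1L)
  srow <- matrix(rd_f32(280L, 12L), nrow = 3, byrow = TRUE)
  if (sform_code > 0L) {
    affine <- rbind(srow, c(0, 0, 0, 1))
  } else {
    affine <- diag(c(abs(pixdim[2:4]), 1))
  }
  # skip extension bytes up to vox_offset
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(shape)
  vals <- readBin(con, tp$what, n, tp$size, signed = tp$signed, endian = endian)
  assert_that(length(vals) == n, "truncated NIfTI data in %s", path,
              class = "bxs_format_error")
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  volume_grid(array(vals, dim = shape), affine)
}

#' Write a NIfTI-1 volume
#'
#' Integer-mode arrays are stored as int32 (bit-exact round trip); doubles as
#' float64.  The affine is written as an sform (code 1), little-endian.
#'
#' @param vol a [volume_grid].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  assert_that(inherits(vol, "volume_grid"), "vol must be a volume_grid")
  vals <- vol$values
  if (is.integer(vals) || is.logical(vals)) {
    datatype <- 8L; bitpix <- 32L; what <- "integer"; size <- 4L
    vals <- as.integer(vals)
  } else {
    datatype <- 64L; bitpix <- 64L; what <- "double"; size <- 8L
    vals <- as.double(vals)
  }
  shape <- dim(vol$values)
  ndim <- length(shape)
  dim0 <- integer(8)
  dim0[1] <- ndim
  dim0[2:(1 + ndim)] <- shape
  dim0[(2 + ndim):8] <- 1L
  vsz <- voxel_size(vol)
  pixdim <- c(1, vsz, rep(1, 4))[1:8]

  con <- nii_connection(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                      # sizeof_hdr
  w_raw(36L)                       # data_type[10], db_name[18], extents, session_error, regular, dim_info
  w_i16(dim0)                      # dim[8]
  w_f32(c(0, 0, 0))                # intent_p1..p3
  w_i16(0L)                        # intent_code
  w_i16(datatype)                  # datatype
  w_i16(bitpix)                    # bitpix
  w_i16(0L)                        # slice_start
  w_f32(pixdim)                    # pixdim[8]
  w_f32(352)                       # vox_offset
  w_f32(1)                         # scl_slope
  w_f32(0)                         # scl_inter
  w_i16(0L); w_raw(2L)             # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0))                # cal_max, cal_min, slice_duration
  w_f32(0)                         # toffset
  w_i32(c(0L, 0L))                 # glmax, glmin
  w_raw(104L)                      # descrip[80] + aux_file[24]
  w_i16(0L)                        # qform_code
  w_i16(1L)                        # sform_code
  w_f32(c(0, 0, 0, 0, 0, 0))      # quatern_b..d, qoffset_x..z
  aff <- vol$affine
  w_f32(aff[1, ]); w_f32(aff[2, ]); w_f32(aff[3, ])  # srow_x/y/z
  w_raw(16L)                       # intent_name[16]
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)     # magic "n+1\0" -> 348 bytes
  w_raw(4L)                                          # extension flag -> vox_offset 352
  writeBin(vals, con, size, endian = "little")
  invisible(path)
}
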