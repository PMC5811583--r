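# Minimal NIfTI-1 single-file (.nii / .nii.gz) codec for 3-D quantitative
# images and 0/1 masks. Covers the subset this pipeline needs: 348-byte
# header, sform affine restricted to a diagonal spacing matrix plus origin,
# datatypes uint8/int16/int32/float32/float64, scl_slope/scl_inter scaling,
# and both byte orders on read. Images are written as float64 so activity
# round-trips exactly; masks as uint8.

NIFTI_DT <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double",  size = 4L, signed = TRUE),
  `64` = list(what = "double",  size = 8L, signed = TRUE)
)

nifti_header_raw <- function(dims, spacing, origin, datatype, bitpix) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348)                                   # sizeof_hdr
  w_raw(36)                                    # data_type..dim_info (unused)
  w_i16(c(3, dims, 1, 1, 1, 1))                # dim[8]
  w_f32(c(0, 0, 0))                            # intent_p1..p3
  w_i16(0)                                     # intent_code
  w_i16(datatype)                              # datatype
  w_i16(bitpix)                                # bitpix
  w_i16(0)                                     # slice_start
  w_f32(c(1, spacing, 0, 0, 0, 0))             # pixdim[8], qfac = 1
  w_f32(352)                                   # vox_offset
  w_f32(1)                                     # scl_slope
  w_f32(0)                                     # scl_inter
  w_i16(0)                                     # slice_end
  writeBin(as.raw(c(0, 2)), con)               # slice_code, xyzt_units = mm
  w_f32(c(0, 0, 0, 0))                         # cal_max..toffset
  w_i32(c(0, 0))                               # glmax, glmin
  w_raw(80 + 24)                               # descrip, aux_file
  w_i16(0)                                     # qform_code
  w_i16(1)                                     # sform_code
  w_f32(c(0, 0, 0))                            # quatern_b, c, d
  w_f32(origin)                                # qoffset_x, y, z
  w_f32(c(spacing[1], 0, 0, origin[1]))        # srow_x
  w_f32(c(0, spacing[2], 0, origin[2]))        # srow_y
  w_f32(c(0, 0, spacing[3], origin[3]))        # srow_z
  w_raw(16)                                    # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  rawConnectionValue(con)
}

open_nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a voxel image to NIfTI-1
#'
#' Values are stored as float64 so activity round-trips bit-exactly; the
#' voxel spacing goes to `pixdim` and a diagonal sform, the origin to the
#' sform translation column.
#'
#' @param image a [voxel_image()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (!inherits(image, "voxel_image")) stop("`image` must be a voxel_image")
  hdr <- nifti_header_raw(dim(image$values), image$spacing, image$origin,
                          datatype = 64L, bitpix = 64L)
  con <- open_nifti_con(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con)  # no header extensions
  writeBin(as.numeric(image$values), con, size = 8L, endian = "little")
  invisible(path)
}

#' Write an ROI mask to NIfTI-1
#'
#' Masks are stored as 0/1 uint8 volumes on the grid of the image they
#' annotate.
#'
#' @param mask an [roi_mask()] over a 3-D grid.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param spacing,origin grid geometry of the annotated image (mm).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!inherits(mask, "roi_mask")) stop("`mask` must be an roi_mask")
  if (length(dim(mask$selected)) != 3L) stop("NIfTI masks must be 3-D")
  hdr <- nifti_header_raw(dim(mask$selected), spacing, origin,
                          datatype = 2L, bitpix = 8L)
  con <- open_nifti_con(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con)
  writeBin(as.integer(mask$selected), con, size = 1L)
  invisible(path)
}

read_nifti <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  con <- open_nifti_con(path, "rb")
  on.exit(close(con))
  sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(sz) == 0) stop("malformed NIfTI file ", path, ": empty file")
  endian <- "little"
  if (sz != 348L) {
    sz_big <- readBin(rev(writeBin(as.integer(sz), raw())), "integer",
                      size = 4L, endian = "little")
    if (sz_big == 348L) endian <- "big"
    else stop("malformed NIfTI file ", path, ": sizeof_hdr is ", sz, ", not 348")
  }
  rest <- readBin(con, "raw", 344L)
  if (length(rest) < 344L) stop("malformed NIfTI file ", path, ": truncated header")
  hdr <- c(writeBin(348L, raw(), size = 4L, endian = endian), rest)
  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1L):(off + n * size)], what, n, size = size,
            endian = endian, signed = TRUE)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    stop("malformed NIfTI file ", path, ": bad magic '", magic, "'")
  }
  dims <- rd(40L, "integer", 8L, 2L)
  ndim <- dims[1]
  if (ndim < 2L || ndim > 7L) {
    stop("malformed NIfTI file ", path, ": dim[0] = ", ndim)
  }
  shape <- dims[2:(1 + ndim)]
  if (ndim > 3L && any(shape[4:ndim] != 1L)) {
    stop("unsupported NIfTI file ", path, ": more than 3 non-singleton dims")
  }
  shape <- shape[1:min(ndim, 3L)]
  datatype <- rd(70L, "integer", 1L, 2L)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) {
    stop("unsupported NIfTI datatype ", datatype, " in ", path)
  }
  pixdim <- rd(76L, "double", 8L, 4L)
  vox_offset <- rd(108L, "double", 1L, 4L)
  scl_slope <- rd(112L, "double", 1L, 4L)
  scl_inter <- rd(116L, "double", 1L, 4L)
  qform_code <- rd(252L, "integer", 1L, 2L)
  sform_code <- rd(254L, "integer", 1L, 2L)
  origin <- c(0, 0, 0)
  if (sform_code > 0L) {
    origin <- c(rd(280L, "double", 4L, 4L)[4],
                rd(296L, "double", 4L, 4L)[4],
                rd(312L, "double", 4L, 4L)[4])
  } else if (qform_code > 0L) {
    origin <- rd(268L, "double", 3L, 4L)
  }
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(shape)
  vals <- if (dt$what == "integer" && dt$size == 1L) {
    as.double(readBin(con, "integer", n, size = 1L, signed = FALSE, endian = endian))
  } else if (dt$what == "integer") {
    as.double(readBin(con, "integer", n, size = dt$size, endian = endian))
  } else {
    readBin(con, "double", n, size = dt$size, endian = endian)
  }
  if (length(vals) < n) stop("malformed NIfTI file ", path, ": truncated data")
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  list(
    values = array(vals, dim = shape),
    spacing = abs(pixdim[2:(1 + length(shape))]),
    origin = origin
  )
}

#' Read a voxel image from NIfTI-1
#'
#' @param path a `.nii` or `.nii.gz` file with a 3-D volume.
#' @return A [voxel_image()] with the file's values (Bq), spacing, and
#'   sform/qform origin.
#' @export
read_image <- function(path) {
  x <- read_nifti(path)
  if (length(dim(x$values)) != 3L) {
    stop("expected a 3-D volume in ", path, ", got ",
         length(dim(x$values)), " dims")
  }
  voxel_image(x$values, spacing = x$spacing, origin = x$origin)
}

#' Read an ROI mask from NIfTI-1
#'
#' Any nonzero voxel is selected.
#'
#' @param path a `.nii` or `.nii.gz` file with a 0/1 volume.
#' @param label ROI name recorded on the mask.
#' @return An [roi_mask()].
#' @export
read_mask <- function(path, label = basename(path)) {
  x <- read_nifti(path)
  roi_mask(x$values != 0, label = label)
}
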