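# Minimal NIfTI-1 (.nii / .nii.gz) I/O for cubic volumes: float32 images and
# uint8 masks, isotropic spacing from pixdim, offset from qoffset (qform code
# 1, identity rotation). No R NIfTI package is available in the target
# environment, so the 348-byte header is read/written directly.

.nifti_write_header <- function(con, dims, pixdim, origin, datatype, bitpix) {
  writeBin(348L, con, size = 4)                       # sizeof_hdr
  writeBin(raw(35), con)                              # data_type..regular
  writeBin(raw(1), con)                               # dim_info
  writeBin(as.integer(c(3L, dims, 1L, 1L, 1L, 1L)), con, size = 2)  # dim[8]
  writeBin(numeric(3), con, size = 4)                 # intent_p1..p3
  writeBin(0L, con, size = 2)                         # intent_code
  writeBin(as.integer(datatype), con, size = 2)
  writeBin(as.integer(bitpix), con, size = 2)
  writeBin(0L, con, size = 2)                         # slice_start
  writeBin(c(1, rep(pixdim, 3), 1, 1, 1, 1), con, size = 4)  # pixdim[8]
  writeBin(352, con, size = 4)                        # vox_offset
  writeBin(c(1, 0), con, size = 4)                    # scl_slope, scl_inter
  writeBin(0L, con, size = 2); writeBin(raw(2), con)  # slice_end, slice_code, xyzt_units
  writeBin(numeric(4), con, size = 4)                 # cal_max..toffset
  writeBin(integer(2), con, size = 4)                 # glmax, glmin
  writeBin(raw(104), con)                             # descrip + aux_file
  writeBin(c(1L, 0L), con, size = 2)                  # qform_code, sform_code
  writeBin(c(0, 0, 0, origin), con, size = 4)         # quatern b,c,d + qoffset
  writeBin(numeric(12), con, size = 4)                # srow
  writeBin(raw(16), con)                              # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con)  # magic
  writeBin(raw(4), con)                               # extension flag
}

#' Write an image volume or mask as NIfTI-1
#'
#' @param img an `image_volume`, or a 3D numeric/integer array.
#' @param path output path; gzip-compressed when it ends in `.gz`.
#' @param spacing,origin used when `img` is a bare array.
#' @param mask write as uint8 (for binary masks) instead of float32.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, spacing = 1.0, origin = c(0, 0, 0),
                        mask = FALSE) {
  if (inherits(img, "image_volume")) {
    spacing <- img$spacing; origin <- img$origin; img <- img$voxels
  }
  stopifnot(length(dim(img)) == 3L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (mask) {
    .nifti_write_header(con, dim(img), spacing, origin, 2L, 8L)
    writeBin(as.raw(as.integer(img) != 0L), con)
  } else {
    .nifti_write_header(con, dim(img), spacing, origin, 16L, 32L)
    writeBin(as.numeric(img), con, size = 4)
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports the subset written by [write_nifti()]: single-file `.nii`/.`nii.gz`
#' with float32, float64, uint8, or int16 data and isotropic spacing.
#'
#' @param path input path.
#' @return an `image_volume` (mask volumes come back as numeric 0/1).
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  sz <- readBin(hdr[1:4], "integer", 1, size = 4)
  if (sz != 348L) stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  dimv <- readBin(hdr[41:56], "integer", 8, size = 2)
  dims <- dimv[2:(1 + dimv[1])]
  if (length(dims) != 3L) stop("only 3D NIfTI volumes are supported")
  datatype <- readBin(hdr[71:72], "integer", 1, size = 2)
  pixdim <- readBin(hdr[77:108], "numeric", 8, size = 4)
  vox_offset <- readBin(hdr[109:112], "numeric", 1, size = 4)
  qoffset <- readBin(hdr[269:280], "numeric", 3, size = 4)
  if (vox_offset > 352) readBin(con, "raw", vox_offset - 352)
  n <- prod(dims)
  vox <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", n, size = 2)),
    "16" = readBin(con, "numeric", n, size = 4),
    "64" = readBin(con, "numeric", n, size = 8),
    stop("unsupported NIfTI datatype: ", datatype))
  image_volume(array(vox, dims), spacing = pixdim[2], origin = qoffset)
}
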