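## Minimal single-file NIfTI-1 I/O.
##
## The parcellated pipeline is TSV-first; voxel images only enter through
## atlas label volumes, 4D BOLD and PET maps, all of which fit comfortably in
## uncompressed little-endian .nii with no extensions. No NIfTI package is
## available in the target R stack, so this implements exactly that subset:
## datatypes int16/int32/float32/float64, magic "n+1", vox_offset 352.

NIFTI_DT <- list(int16 = 4L, int32 = 8L, float32 = 16L, float64 = 64L)
NIFTI_BITPIX <- c(`4` = 16L, `8` = 32L, `16` = 32L, `64` = 64L)

#' Write a 3D or 4D array as an uncompressed NIfTI-1 image
#'
#' @param img numeric or integer array with 3 or 4 dimensions.
#' @param path output file path (`.nii`).
#' @param pixdim voxel sizes, recycled to the number of dimensions; the 4th
#'   entry is the repetition time in seconds for 4D images.
#' @param datatype one of `"int16"`, `"int32"`, `"float32"`, `"float64"`.
#'   Defaults to `"int32"` for integer data and `"float64"` otherwise.
#' @return `path`, invisibly.
#' @export
nifti_write <- function(img, path, pixdim = 1, datatype = NULL) {
  nd <- length(dim(img))
  if (is.null(dim(img)) || nd < 3L || nd > 4L)
    stop_validation("nifti_write expects a 3D or 4D array")
  if (is.null(datatype)) datatype <- if (is.integer(img)) "int32" else "float64"
  code <- NIFTI_DT[[datatype]]
  if (is.null(code)) stop_validation("unsupported datatype: ", datatype)
  dims <- integer(8); dims[1] <- nd; dims[2:(1 + nd)] <- dim(img)
  dims[dims == 0L] <- 1L
  pd <- numeric(8); pd[1] <- 1
  pd[2:(1 + nd)] <- rep_len(pixdim, nd)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)                      # sizeof_hdr
  writeBin(raw(36), con)                             # unused historical fields
  writeBin(dims, con, size = 2)                      # dim[8]
  writeBin(raw(14), con)                             # intent_p1..3, intent_code
  writeBin(c(code, NIFTI_BITPIX[[as.character(code)]]), con, size = 2)
  writeBin(0L, con, size = 2)                        # slice_start
  writeBin(pd, con, size = 4)                        # pixdim[8]
  writeBin(352, con, size = 4)                       # vox_offset (float)
  writeBin(c(0, 0), con, size = 4)                   # scl_slope, scl_inter
  writeBin(raw(2 + 1 + 1), con)                      # slice_end, slice_code, xyzt_units
  writeBin(c(0, 0, 0), con, size = 4)                # cal_max, cal_min, slice_duration
  writeBin(0, con, size = 4)                         # toffset
  writeBin(c(0L, 0L), con, size = 4)                 # glmax, glmin
  writeBin(raw(80 + 24), con)                        # descrip, aux_file
  writeBin(c(0L, 0L), con, size = 2)                 # qform_code, sform_code
  writeBin(numeric(18), con, size = 4)               # quatern/qoffset + srow
  writeBin(raw(16 + 16), con)                        # intent_name, (into magic)
  seek(con, 344)
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con)
  writeBin(raw(4), con)                              # extension flag
  storage <- if (code %in% c(4L, 8L)) as.integer(round(img)) else as.numeric(img)
  writeBin(storage, con, size = NIFTI_BITPIX[[as.character(code)]] / 8L)
  invisible(path)
}

#' Read an uncompressed NIfTI-1 image written by [nifti_write()]
#'
#' @param path `.nii` file path.
#' @return list with `data` (array), `pixdim` (numeric vector per dimension)
#'   and `datatype`.
#' @export
nifti_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sz <- readBin(con, "integer", 1, size = 4)
  if (!identical(sz, 348L))
    stop_validation("not a little-endian NIfTI-1 file: ", path)
  seek(con, 40)
  dims <- readBin(con, "integer", 8, size = 2)
  seek(con, 70)
  code <- readBin(con, "integer", 1, size = 2)
  seek(con, 76)
  pd <- readBin(con, "numeric", 8, size = 4)
  vox_offset <- readBin(con, "numeric", 1, size = 4)
  nd <- dims[1]
  if (nd < 3L || nd > 4L) stop_validation("only 3D/4D NIfTI supported")
  shape <- dims[2:(1 + nd)]
  n <- prod(shape)
  seek(con, vox_offset)
  data <- switch(as.character(code),
    `4`  = readBin(con, "integer", n, size = 2),
    `8`  = readBin(con, "integer", n, size = 4),
    `16` = readBin(con, "numeric", n, size = 4),
    `64` = readBin(con, "numeric", n, size = 8),
    stop_validation("unsupported NIfTI datatype code: ", code))
  list(data = array(data, dim = shape),
       pixdim = pd[2:(1 + nd)],
       datatype = names(NIFTI_DT)[match(code, unlist(NIFTI_DT))])
}
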