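# Minimal NIfTI-1 reader/writer.
#
# No NIfTI package is assumed to be installed, so the single-file .nii
# layout (348-byte header, data at byte 352) is read and written
# directly. Only what the bullseye mapper needs is supported: 2D/3D
# volumes, datatypes uint8/int16/int32/float32/float64, sform affines,
# optional gzip (.nii.gz). Scaling (scl_slope/scl_inter) is honoured on
# read; writing always uses float32 with an sform built from the affine.

nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "numeric", size = 4L, signed = TRUE),
  `64` = list(what = "numeric", size = 8L, signed = TRUE)
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return a [label_volume()] (the grid holds the stored values; apply
#'   your own thresholds for probabilistic maps).
#' @export
read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1, 4)
  if (sizeof_hdr != 348L) stop(path, " is not a NIfTI-1 file (sizeof_hdr != 348)")
  readBin(con, "raw", 36)                      # unused legacy fields + dim_info
  dims <- readBin(con, "integer", 8, 2)
  ndim <- dims[1]
  if (!ndim %in% 2:3) stop("only 2D/3D NIfTI volumes are supported (ndim=", ndim, ")")
  shape <- dims[2:(1 + ndim)]
  readBin(con, "raw", 14)                      # intent_p1..3, intent_code
  datatype <- readBin(con, "integer", 1, 2)
  readBin(con, "integer", 1, 2)                # bitpix
  readBin(con, "integer", 1, 2)                # slice_start
  pixdim <- readBin(con, "numeric", 8, 4)
  vox_offset <- readBin(con, "numeric", 1, 4)
  scl_slope <- readBin(con, "numeric", 1, 4)
  scl_inter <- readBin(con, "numeric", 1, 4)
  readBin(con, "raw", 132)                     # slice/cal/descrip/aux fields
  readBin(con, "integer", 1, 2)                # qform_code
  sform_code <- readBin(con, "integer", 1, 2)
  readBin(con, "numeric", 6, 4)                # quaternion fields
  srow <- matrix(readBin(con, "numeric", 12, 4), 3, 4, byrow = TRUE)
  readBin(con, "raw", 20)                      # intent_name + magic
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)

  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  n <- prod(shape)
  x <- readBin(con, dt$what, n, dt$size, signed = dt$signed)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    x <- x * scl_slope + scl_inter
  grid <- array(x, dim = shape)
  affine <- if (sform_code > 0) rbind(srow, c(0, 0, 0, 1)) else NULL
  label_volume(grid, voxel_dims = pixdim[2:(1 + ndim)], affine = affine)
}

#' Write a [label_volume()] as NIfTI-1 (float32)
#'
#' @param vol a [label_volume()].
#' @param path output `.nii` or `.nii.gz` path.
#' @export
write_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  shape <- dim(vol$grid)
  ndim <- length(shape)
  dims <- integer(8); dims[1] <- ndim; dims[2:(1 + ndim)] <- shape
  dims[dims == 0] <- 1L
  pixdim <- numeric(8); pixdim[2:(1 + ndim)] <- vol$voxel_dims
  pixdim[pixdim == 0] <- 1
  aff <- vol$affine %||% {
    a <- diag(4); diag(a)[seq_len(ndim)] <- vol$voxel_dims; a
  }
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, 4)
  writeBin(raw(36), con)                          # data_type..dim_info
  writeBin(as.integer(dims), con, 2)
  writeBin(numeric(3), con, 4)                    # intent_p1..3
  writeBin(0L, con, 2)                            # intent_code
  writeBin(16L, con, 2)                           # datatype float32
  writeBin(32L, con, 2)                           # bitpix
  writeBin(0L, con, 2)                            # slice_start
  writeBin(pixdim, con, 4)
  writeBin(352, con, 4)                           # vox_offset
  writeBin(c(1, 0), con, 4)                       # scl_slope, scl_inter
  writeBin(0L, con, 2); writeBin(raw(2), con)     # slice_end/code/xyzt
  writeBin(numeric(4), con, 4)                    # cal_max/min, slice_dur, toffset
  writeBin(integer(2), con, 4)                    # glmax, glmin
  writeBin(raw(104), con)                         # descrip + aux_file
  writeBin(c(0L, 1L), con, 2)                     # qform_code=0, sform_code=1
  writeBin(numeric(6), con, 4)                    # quaternion fields
  writeBin(as.numeric(t(aff[1:3, ])), con, 4)     # srow_x/y/z
  writeBin(raw(16), con)                          # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con)
  writeBin(raw(4), con)                           # extension flag
  writeBin(as.numeric(vol$grid), con, 4)
  invisible(path)
}
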