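#' Minimal NIfTI-1 volume I/O
#'
#' Self-contained reader/writer for single-file NIfTI-1 (`.nii`, `.nii.gz`)
#' volumes, covering the subset of the format this package produces and
#' consumes: 3D/4D arrays with datatypes uint8, int16, int32, float32,
#' float64; orientation taken from the sform (falling back to the qform
#' offset + pixdim when `sform_code == 0`). Written files use float32 (or
#' uint8 for logical data) with `sform_code = qform_code = 2`.
#'
#' These functions exist because gradient analyses exchange masks, rank maps
#' and statistic maps as NIfTI volumes; they are not a general-purpose NIfTI
#' library (no extensions, no scl slopes other than identity pass-through).
#'
#' @name nifti_io
NULL

nifti_dtypes <- list(
  "2"  = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  "4"  = list(what = "integer", size = 2L, signed = TRUE),   # int16
  "8"  = list(what = "integer", size = 4L, signed = TRUE),   # int32
  "16" = list(what = "double",  size = 4L, signed = TRUE),   # float32
  "64" = list(what = "double",  size = 8L, signed = TRUE),   # float64
  "512" = list(what = "integer", size = 2L, signed = FALSE), # uint16
  "256" = list(what = "integer", size = 1L, signed = TRUE)   # int8
)

#' Read a NIfTI-1 volume
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return list with `data` (numeric array), `grid` ([volume_grid()] built
#'   from the first three dimensions), and `dim` (full stored dim vector).
#' @export
read_nifti <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) != 348L) stop("not a NIfTI-1 file (short header): ", path)
  at <- function(off, len) hdr[(off + 1L):(off + len)]  # off is 0-based
  endian <- "little"
  if (readBin(at(0L, 4L), "integer", 1L, size = 4L, endian = endian) != 348L) {
    endian <- "big"
    if (readBin(at(0L, 4L), "integer", 1L, size = 4L, endian = endian) != 348L)
      stop("not a NIfTI-1 file: ", path)
  }
  rd_i16 <- function(off, n) readBin(at(off, 2L * n), "integer", n, size = 2L,
                                     endian = endian)
  rd_f32 <- function(off, n) readBin(at(off, 4L * n), "numeric", n, size = 4L,
                                     endian = endian)
  dim0 <- rd_i16(40L, 8L)
  datatype <- rd_i16(70L, 1L)
  pixdim <- rd_f32(76L, 8L)
  vox_offset <- rd_f32(108L, 1L)
  scl_slope <- rd_f32(112L, 1L)
  scl_inter <- rd_f32(116L, 1L)
  qform_code <- rd_i16(252L, 1L)
  sform_code <- rd_i16(254L, 1L)
  quat <- rd_f32(256L, 6L)
  srow <- matrix(rd_f32(280L, 12L), nrow = 3L, byrow = TRUE)
  nd <- dim0[1L]
  if (nd < 3L || nd > 4L) stop("only 3D/4D NIfTI supported (ndim=", nd, ")")
  dims <- dim0[2L:(1L + nd)]
  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", as.integer(skip))
  n <- prod(dims)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) != n) stop("truncated NIfTI data in ", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  data <- array(vals, dim = dims)
  affine <- diag(4)
  if (sform_code > 0L) {
    affine[1:3, ] <- srow
  } else {
    # fall back to pixdim scaling with the qform offset; ignores rotation
    affine[1, 1] <- pixdim[2L]; affine[2, 2] <- pixdim[3L]
    affine[3, 3] <- pixdim[4L]
    affine[1:3, 4] <- quat[4:6]
    if (qform_code == 0L) affine[1:3, 4] <- 0
  }
  list(data = data, grid = volume_grid(dims[1:3], affine), dim = dims)
}

#' Write a NIfTI-1 volume
#'
#' @param data numeric or logical 3D/4D array (or a [binary_mask()]).
#' @param path output path; `.gz` suffix selects gzip compression.
#' @param grid optional [volume_grid()] giving the affine; defaults to the
#'   mask's grid or identity spacing.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, grid = NULL) {
  if (inherits(data, "binary_mask")) {
    if (is.null(grid)) grid <- data$grid
    data <- data$values
  }
  dims <- dim(data)
  if (is.null(dims) || !length(dims) %in% c(3L, 4L))
    stop("`data` must be a 3D or 4D array")
  if (is.null(grid)) grid <- volume_grid(dims[1:3])
  logical_data <- is.logical(data)
  datatype <- if (logical_data) 2L else 16L
  bitpix <- if (logical_data) 8L else 32L
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4L)                      # sizeof_hdr
  writeBin(raw(36L), con)
  nd <- length(dims)
  dim0 <- integer(8L); dim0[1L] <- nd; dim0[2L:(1L + nd)] <- dims
  dim0[dim0 == 0L] <- 1L; dim0[1L] <- nd
  writeBin(as.integer(dim0), con, size = 2L)
  writeBin(raw(14L), con)                             # intent fields
  writeBin(as.integer(datatype), con, size = 2L)
  writeBin(as.integer(bitpix), con, size = 2L)
  writeBin(0L, con, size = 2L)                        # slice_start
  pixdim <- numeric(8L); pixdim[1L] <- 1
  pixdim[2:4] <- grid$voxel_size
  if (nd == 4L) pixdim[5L] <- 1
  writeBin(pixdim, con, size = 4L)
  writeBin(352, con, size = 4L)                       # vox_offset
  writeBin(c(1, 0, 0), con, size = 4L)  # scl_slope, scl_inter, slice_end..xyzt
  ## cal_max cal_min slice_duration toffset glmax glmin (6 x 4 bytes)
  writeBin(numeric(4L), con, size = 4L)
  writeBin(integer(2L), con, size = 4L)
  writeBin(charToRaw(sprintf("%-80s", "gradparc")), con)     # descrip
  writeBin(raw(24L), con)                             # aux_file
  writeBin(2L, con, size = 2L)                        # qform_code
  writeBin(2L, con, size = 2L)                        # sform_code
  quat <- c(0, 0, 0, grid$affine[1:3, 4])
  writeBin(quat, con, size = 4L)
  writeBin(as.numeric(t(grid$affine[1:3, ])), con, size = 4L)  # srow_x/y/z
  writeBin(raw(16L), con)                             # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)      # magic
  writeBin(raw(4L), con)                              # pad to vox_offset 352
  if (logical_data) {
    writeBin(as.integer(data), con, size = 1L)
  } else {
    writeBin(as.numeric(data), con, size = 4L)
  }
  invisible(path)
}
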