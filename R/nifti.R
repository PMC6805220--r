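#' Minimal NIfTI-1 input/output
#'
#' Single-file (\code{.nii}), little-endian NIfTI-1 support sufficient for
#' this package's pipeline: 3D masks and 4D BOLD runs, with the grid affine
#' stored in the sform. Only a small set of datatypes is handled
#' (uint8, int16, int32, float32, float64); data are written as float32
#' (masks as uint8). Gzipped files (\code{.nii.gz}) are read and written
#' transparently via R's \code{gzfile}.
#'
#' @name nifti_io
NULL

.nifti_dtypes <- data.frame(
  code  = c(2L, 4L, 8L, 16L, 64L),
  what  = c("integer", "integer", "integer", "numeric", "numeric"),
  size  = c(1L, 2L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE)
)

.nifti_con <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 3D or 4D array as a NIfTI-1 file
#'
#' @param x numeric/logical array (3D or 4D).
#' @param path output path ending in \code{.nii} or \code{.nii.gz}.
#' @param grid a \code{\link{volume_grid}} giving voxel size and affine.
#' @param tr repetition time in seconds (stored in pixdim[4] for 4D data).
#' @param datatype \code{"float32"} (default) or \code{"uint8"}.
#' @return \code{path}, invisibly.
#' @export
write_nifti <- function(x, path, grid, tr = 0, datatype = c("float32", "uint8")) {
  datatype <- match.arg(datatype)
  dims <- dim(x)
  if (is.null(dims) || !(length(dims) %in% c(3L, 4L)))
    stop("x must be a 3D or 4D array")
  stopifnot(all(dims[1:3] == grid$shape))
  ndim <- length(dims)
  dim_field <- rep(1L, 8L)
  dim_field[1] <- ndim
  dim_field[seq_len(ndim) + 1L] <- dims
  pixdim <- rep(0, 8)
  pixdim[1] <- 1  # qfac
  pixdim[2:4] <- grid$voxel_mm
  if (ndim == 4L) pixdim[5] <- tr
  dt_code <- if (datatype == "float32") 16L else 2L
  bitpix <- if (datatype == "float32") 32L else 8L

  con <- .nifti_con(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4, endian = "little")          # sizeof_hdr
  writeBin(raw(36), con)                                    # unused
  writeBin(as.integer(dim_field), con, size = 2, endian = "little")
  writeBin(raw(14), con)                                    # intent_p*, intent_code
  writeBin(c(dt_code, bitpix, 0L), con, size = 2, endian = "little")
  writeBin(pixdim, con, size = 4, endian = "little")
  writeBin(352, con, size = 4, endian = "little")           # vox_offset (float)
  writeBin(c(1, 0), con, size = 4, endian = "little")       # scl_slope, scl_inter
  writeBin(raw(3), con)                                     # slice_end, slice_code, xyzt_units
  writeBin(as.raw(10L), con)                                # xyzt_units: mm | sec
  writeBin(raw(24), con)                                    # cal_max..glmin
  writeBin(raw(104), con)                                   # descrip + aux_file
  writeBin(c(0L, 1L), con, size = 2, endian = "little")     # qform_code=0, sform_code=1
  writeBin(rep(0, 6), con, size = 4, endian = "little")     # quaternions
  writeBin(as.numeric(t(grid$affine[1:3, ])), con, size = 4, endian = "little")
  writeBin(raw(16), con)                                    # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)             # magic
  writeBin(raw(4), con)                                     # extension flag -> offset 352
  if (datatype == "float32") {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(x), con, size = 1, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file
#'
#' @param path file written by \code{\link{write_nifti}} or any
#'   single-file little-endian NIfTI-1 image of a supported datatype.
#' @return list with \code{data} (array), \code{grid}
#'   (\code{\link{volume_grid}}) and \code{tr} (seconds; 0 for 3D).
#' @export
read_nifti <- function(path) {
  con <- .nifti_con(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(hdr_size, 348L))
    stop("not a little-endian NIfTI-1 file: ", path)
  invisible(readBin(con, "raw", 36))
  dim_field <- readBin(con, "integer", 8, size = 2, endian = "little")
  invisible(readBin(con, "raw", 14))
  dt <- readBin(con, "integer", 3, size = 2, endian = "little")
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = "little")
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = "little")
  scl <- readBin(con, "numeric", 2, size = 4, endian = "little")
  invisible(readBin(con, "raw", 132))
  codes <- readBin(con, "integer", 2, size = 2, endian = "little")
  invisible(readBin(con, "numeric", 6, size = 4, endian = "little"))
  srow <- readBin(con, "numeric", 12, size = 4, endian = "little")
  invisible(readBin(con, "raw", 16))
  magic <- rawToChar(readBin(con, "raw", 4)[1:3])
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic in ", path)

  ndim <- dim_field[1]
  dims <- dim_field[seq_len(ndim) + 1L]
  spec <- .nifti_dtypes[.nifti_dtypes$code == dt[1], ]
  if (nrow(spec) != 1L) stop("unsupported NIfTI datatype code ", dt[1])
  n <- prod(dims)
  # skip to vox_offset
  already <- 348L
  skip <- round(vox_offset) - already
  if (skip > 0) invisible(readBin(con, "raw", skip))
  vals <- readBin(con, spec$what, n, size = spec$size,
                  signed = spec$signed, endian = "little")
  if (length(vals) != n)
    stop("truncated NIfTI data in ", path, ": expected ", n, " values, got ",
         length(vals))
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0))
    vals <- vals * scl[1] + scl[2]
  data <- array(vals, dim = dims)

  affine <- diag(4)
  if (codes[2] > 0) {
    affine[1:3, ] <- matrix(srow, nrow = 3, byrow = TRUE)
  } else {
    affine[1:3, 1:3] <- diag(pixdim[2:4], 3)
  }
  voxel_mm <- sqrt(colSums(affine[1:3, 1:3]^2))
  grid <- volume_grid(dims[1:3], voxel_mm = voxel_mm)
  grid$affine <- affine
  list(data = data, grid = grid,
       tr = if (ndim >= 4L) pixdim[5] else 0)
}
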