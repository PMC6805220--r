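#' Voxel grid geometry
#'
#' A \code{volume_grid} describes the geometry shared by all images in an
#' analysis: the array shape, the voxel size in mm, and the affine mapping
#' zero-based voxel indices to world (mm) coordinates.
#'
#' @param shape integer vector of length 3 (nx, ny, nz).
#' @param voxel_mm voxel edge lengths in mm; a scalar is recycled to 3
#'   (default 3 mm isotropic).
#' @param origin_mm world coordinate of voxel (0, 0, 0); defaults to the
#'   grid centre so that world (0,0,0) is mid-volume.
#' @return An object of class \code{volume_grid} with fields \code{shape},
#'   \code{voxel_mm} and \code{affine} (4 x 4).
#' @examples
#' g <- volume_grid(c(30, 36, 24))
#' voxel_to_mm(g, c(0, 0, 0))
#' @export
volume_grid <- function(shape, voxel_mm = 3, origin_mm = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  if (any(voxel_mm <= 0)) stop("voxel size must be > 0")
  if (is.null(origin_mm)) origin_mm <- -voxel_mm * (shape - 1) / 2
  affine <- diag(4)
  affine[1:3, 1:3] <- diag(voxel_mm, 3)
  affine[1:3, 4] <- origin_mm
  if (abs(det(affine)) < .Machine$double.eps) stop("affine not invertible")
  structure(list(shape = shape, voxel_mm = voxel_mm, affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %s, voxels %s mm>\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_mm, 3), collapse = "x")))
  invisible(x)
}

#' @export
format.volume_grid <- function(x, ...) {
  sprintf("%s@%smm", paste(x$shape, collapse = "x"),
          paste(signif(x$voxel_mm, 3), collapse = "x"))
}

n_voxels <- function(grid) prod(grid$shape)

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$affine - b$affine) < tol)
}

#' Convert voxel indices to world coordinates
#'
#' @param grid a \code{\link{volume_grid}}.
#' @param ijk matrix (n x 3) or vector of zero-based voxel indices.
#' @return matrix (n x 3) of mm coordinates.
#' @export
voxel_to_mm <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  t(grid$affine[1:3, 1:3] %*% t(ijk) + grid$affine[1:3, 4])
}

#' Convert world coordinates to (zero-based) voxel indices
#'
#' Coordinates are rounded to the containing voxel.
#'
#' @inheritParams voxel_to_mm
#' @param mm matrix (n x 3) or vector of world coordinates.
#' @export
mm_to_voxel <- function(grid, mm) {
  mm <- matrix(as.numeric(mm), ncol = 3)
  inv <- solve(grid$affine)
  round(t(inv[1:3, 1:3] %*% t(mm) + inv[1:3, 4]))
}

#' Region-of-interest mask on a voxel grid
#'
#' @param mask logical array matching \code{grid$shape}, or an integer
#'   vector of (one-based) linear voxel indices.
#' @param grid a \code{\link{volume_grid}}.
#' @param name region label.
#' @param provenance free-form record of how the mask was built
#'   (sphere centre/radius, contrast + threshold, or file path).
#' @return An object of class \code{roi_mask}; the logical array is in
#'   \code{$mask}, linear indices in \code{$idx}.
#' @export
roi_mask <- function(mask, grid, name = "roi", provenance = list()) {
  if (is.logical(mask)) {
    stopifnot(all(dim(mask) == grid$shape))
    idx <- which(mask)
  } else {
    idx <- sort(unique(as.integer(mask)))
    stopifnot(all(idx >= 1L), all(idx <= n_voxels(grid)))
    mask <- array(FALSE, grid$shape)
    mask[idx] <- TRUE
  }
  structure(list(mask = mask, idx = idx, grid = grid, name = name,
                 provenance = provenance),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask '%s': %d voxels on %s>\n", x$name,
              length(x$idx), format(x$grid)))
  invisible(x)
}

#' Number of voxels in an ROI
#' @param roi an \code{roi_mask}.
#' @export
roi_size <- function(roi) length(roi$idx)

#' Union of ROI masks
#' @param ... \code{roi_mask} objects on the same grid.
#' @param name label for the combined mask.
#' @export
roi_union <- function(..., name = "union") {
  rois <- list(...)
  if (length(rois) == 1L && is.list(rois[[1]]) && !inherits(rois[[1]], "roi_mask"))
    rois <- rois[[1]]
  grid <- rois[[1]]$grid
  for (r in rois) stopifnot(grids_equal(grid, r$grid))
  roi_mask(sort(unique(unlist(lapply(rois, `[[`, "idx")))), grid, name = name,
           provenance = list(op = "union", parts = vapply(rois, `[[`, "", "name")))
}

# zero-based ijk coordinates for linear indices (internal)
idx_to_ijk <- function(idx, shape) {
  idx0 <- idx - 1L
  i <- idx0 %% shape[1]
  j <- (idx0 %/% shape[1]) %% shape[2]
  k <- idx0 %/% (shape[1] * shape[2])
  cbind(i, j, k)
}
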