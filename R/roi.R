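#' Spherical ROI on a voxel grid
#'
#' Membership is by voxel-centre distance: the mask contains exactly the
#' voxels whose centre lies within \code{radius_mm} of the centre of the
#' voxel containing \code{center_mm}. On a 3 mm isotropic grid a 5 mm
#' radius yields 19 voxels and the count is invariant under whole-voxel
#' translations of the centre.
#'
#' @param center_mm world coordinate (length 3) of the sphere centre.
#' @param radius_mm sphere radius in mm (0 gives the single centre voxel).
#' @param grid a \code{\link{volume_grid}}.
#' @param name region label.
#' @return an \code{\link{roi_mask}}.
#' @export
sphere_roi <- function(center_mm, radius_mm, grid, name = "sphere") {
  stopifnot(radius_mm >= 0)
  cv <- drop(mm_to_voxel(grid, center_mm))
  if (any(cv < 0) || any(cv > grid$shape - 1L))
    stop("sphere centre outside grid bounds")
  cmm <- drop(voxel_to_mm(grid, cv))
  r_vox <- ceiling(radius_mm / grid$voxel_mm)
  rng <- lapply(1:3, function(d)
    max(0L, cv[d] - r_vox[d]):min(grid$shape[d] - 1L, cv[d] + r_vox[d]))
  ijk <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  mm <- voxel_to_mm(grid, ijk)
  d2 <- rowSums(sweep(mm, 2, cmm)^2)
  keep <- ijk[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
  if (nrow(keep) == 0L) stop("empty sphere mask")
  idx <- keep[, 1] + keep[, 2] * grid$shape[1] +
    keep[, 3] * grid$shape[1] * grid$shape[2] + 1L
  roi_mask(as.integer(idx), grid, name = name,
           provenance = list(type = "sphere", center_mm = center_mm,
                             radius_mm = radius_mm))
}

# paired (one-sample on differences) t statistic per voxel (internal)
.paired_t_map <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  s <- sqrt(colSums(sweep(D, 2, m)^2) / (n - 1))
  list(t = m / (s / sqrt(n)), df = n - 1)
}

#' Localizer-defined category-selective cortex
#'
#' Builds the ventral-temporal analysis mask from per-subject object and
#' scene localizer contrast maps: a voxelwise paired contrast across
#' subjects (groups pooled), thresholded with family-wise error control
#' over the in-mask voxels, taking the union of the object > scene and
#' scene > object suprathreshold voxels intersected with the anatomical
#' mask. FWE control is Bonferroni by default; a sign-flip permutation
#' max-statistic test is available.
#'
#' @param object_maps,scene_maps numeric matrices, one row per subject and
#'   one column per voxel of the grid (or per in-mask voxel, matching
#'   \code{anatomical_mask}).
#' @param anatomical_mask an \code{\link{roi_mask}} restricting the search.
#' @param alpha family-wise error level (default 0.05).
#' @param method \code{"bonferroni"} or \code{"permutation"}.
#' @param n_perm sign-flip permutations when \code{method = "permutation"}.
#' @return an \code{\link{roi_mask}} of the selective voxels.
#' @export
localizer_vtc <- function(object_maps, scene_maps, anatomical_mask,
                          alpha = 0.05, method = c("bonferroni", "permutation"),
                          n_perm = 1000L) {
  method <- match.arg(method)
  object_maps <- as.matrix(object_maps); scene_maps <- as.matrix(scene_maps)
  stopifnot(all(dim(object_maps) == dim(scene_maps)))
  grid <- anatomical_mask$grid
  if (ncol(object_maps) == n_voxels(grid)) {
    object_maps <- object_maps[, anatomical_mask$idx, drop = FALSE]
    scene_maps <- scene_maps[, anatomical_mask$idx, drop = FALSE]
  }
  stopifnot(ncol(object_maps) == roi_size(anatomical_mask))
  D <- object_maps - scene_maps
  tt <- .paired_t_map(D)
  t_obs <- tt$t
  m <- length(t_obs)
  if (method == "bonferroni") {
    # two one-sided tests per voxel, Bonferroni over voxels
    p_pos <- pt(t_obs, tt$df, lower.tail = FALSE)
    p_neg <- pt(t_obs, tt$df, lower.tail = TRUE)
    sel <- pmin(1, m * p_pos) <= alpha | pmin(1, m * p_neg) <= alpha
  } else {
    maxs <- replicate(n_perm, {
      signs <- sample(c(-1, 1), nrow(D), replace = TRUE)
      max(abs(.paired_t_map(D * signs)$t), na.rm = TRUE)
    })
    thr <- stats::quantile(maxs, 1 - alpha, names = FALSE, type = 1)
    sel <- abs(t_obs) >= thr
  }
  sel[is.na(sel)] <- FALSE
  if (!any(sel))
    stop(sprintf("no suprathreshold localizer voxels (max |t| = %.3f)",
                 suppressWarnings(max(abs(t_obs), na.rm = TRUE))))
  roi_mask(anatomical_mask$idx[sel], grid, name = "VTC_localizer",
           provenance = list(type = "localizer", alpha = alpha,
                             method = method, df = tt$df))
}

#' Participant-specific seed sphere at the within-mask contrast peak
#'
#' Finds the voxel with the maximum contrast value inside a search mask
#' (ties broken deterministically by smallest linear voxel index, with a
#' warning) and returns a sphere of the requested radius centred there.
#' The sphere is not clipped to the search mask.
#'
#' @param contrast numeric vector over all grid voxels (or a 3D array) —
#'   e.g. a hits > correct-rejections contrast.
#' @param search_mask an \code{\link{roi_mask}} (e.g. anatomical
#'   hippocampus).
#' @param radius_mm seed radius in mm (default 5).
#' @param subject optional subject id stored in the spec.
#' @return list with \code{spec} (subject, peak voxel index, peak mm
#'   coordinate, peak value, radius) and \code{roi} (the sphere mask).
#' @export
participant_seed <- function(contrast, search_mask, radius_mm = 5,
                             subject = NA_character_) {
  grid <- search_mask$grid
  v <- as.numeric(contrast)
  stopifnot(length(v) == n_voxels(grid))
  vals <- v[search_mask$idx]
  if (all(is.na(vals))) stop("contrast is all-NA within the search mask")
  mx <- max(vals, na.rm = TRUE)
  at <- search_mask$idx[which(vals == mx)]
  if (length(at) > 1L)
    warning("tied contrast maxima (", length(at),
            " voxels); using smallest voxel index")
  peak_idx <- min(at)
  peak_mm <- drop(voxel_to_mm(grid, idx_to_ijk(peak_idx, grid$shape)))
  roi <- sphere_roi(peak_mm, radius_mm, grid,
                    name = paste0("seed_", subject))
  spec <- list(subject = subject, peak_idx = peak_idx, peak_mm = peak_mm,
               peak_value = mx, radius_mm = radius_mm,
               search_mask = search_mask$name)
  list(spec = spec, roi = roi)
}
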