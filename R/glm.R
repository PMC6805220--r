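#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities with peak delay 6 s, undershoot delay
#' 16 s, dispersions 1, undershoot ratio 1/6, support 0-32 s; the kernel is
#' scaled to a peak of 1.
#'
#' @param dt sampling interval in seconds (> 0).
#' @param duration kernel length in seconds (default 32).
#' @return numeric vector sampled at \code{seq(0, duration, by = dt)}.
#' @examples
#' h <- canonical_hrf(0.1)
#' (which.max(h) - 1) * 0.1  # peaks near 5 s
#' @export
canonical_hrf <- function(dt, duration = 32) {
  stopifnot(dt > 0)
  g <- function(t) dgamma(t, shape = 6, rate = 1) -
    dgamma(t, shape = 16, rate = 1) / 6
  t <- seq(0, duration, by = dt)
  # normalise by the continuous peak so any sampling of the kernel is an
  # exact subsample of a finer one
  peak <- stats::optimize(g, c(3, 8), maximum = TRUE)$objective
  g(t) / peak
}

#' Discrete-cosine high-pass filter basis
#'
#' The SPM-convention drift model: cosines \eqn{k = 1, \dots, K} with
#' \eqn{K = \lfloor 2 n T_R / \mathrm{cutoff} \rfloor}, i.e. all
#' components with period longer than the cutoff. The constant term is
#' excluded (it is carried by the session mean).
#'
#' @param n_volumes number of scans.
#' @param tr repetition time (s).
#' @param cutoff_s high-pass cutoff period in seconds (default 128);
#'   \code{Inf} gives an empty basis.
#' @return matrix \code{n_volumes x K} (possibly 0 columns), columns
#'   orthonormal and orthogonal to the constant.
#' @export
highpass_basis <- function(n_volumes, tr, cutoff_s = 128) {
  stopifnot(n_volumes >= 2)
  K <- if (is.infinite(cutoff_s)) 0L else floor(2 * n_volumes * tr / cutoff_s)
  K <- max(0L, min(K, n_volumes - 1L))
  if (K == 0L) return(matrix(0, n_volumes, 0))
  t <- seq_len(n_volumes) - 1L
  X <- sapply(seq_len(K), function(k)
    sqrt(2 / n_volumes) * cos(pi * (2 * t + 1) * k / (2 * n_volumes)))
  colnames(X) <- paste0("dct", seq_len(K))
  X
}

# memoised canonical HRF kernels keyed by dt (internal)
.hrf_cache <- new.env(parent = emptyenv())
.hrf_kernel <- function(dt) {
  key <- format(dt, digits = 12)
  if (is.null(.hrf_cache[[key]])) .hrf_cache[[key]] <- canonical_hrf(dt)
  .hrf_cache[[key]]
}

# HRF-convolved regressor for a set of onsets, sampled at scan starts
# (t = 0, TR, 2 TR, ...); delta-function events on a fine microtime grid.
.reg_cache <- new.env(parent = emptyenv())

.convolved_regressor <- function(onsets, n_volumes, tr, dt = 0.1) {
  run_len <- n_volumes * tr
  if (any(onsets < 0 | onsets >= run_len))
    stop("event onset outside the run (0 to ", run_len, " s)")
  if (length(onsets) == 1L) {
    key <- paste(onsets, n_volumes, tr, dt, sep = "|")
    hit <- .reg_cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  nt <- ceiling(run_len / dt) + 1L
  h <- .hrf_kernel(dt)
  conv <- numeric(nt + length(h))
  # delta events: place the kernel directly at each onset
  for (o in round(onsets / dt) + 1L) {
    span <- o:(o + length(h) - 1L)
    conv[span] <- conv[span] + h
  }
  scan_t <- (seq_len(n_volumes) - 1L) * tr
  out <- conv[round(scan_t / dt) + 1L]
  if (length(onsets) == 1L) .reg_cache[[key]] <- out
  out
}

.motion_columns <- function(motion, n_volumes) {
  if (is.null(motion)) return(matrix(0, n_volumes, 0))
  motion <- as.matrix(motion)
  stopifnot(nrow(motion) == n_volumes)
  keep <- apply(motion, 2, function(x) sd(x) > 0)
  motion <- motion[, keep, drop = FALSE]
  if (ncol(motion) > 0)
    colnames(motion) <- paste0("motion", seq_len(ncol(motion)))
  motion
}

#' Condition-level design matrix for one run
#'
#' One regressor per condition of interest: hits, correct rejections and a
#' catch-all "other" for the remaining trials (misses, false alarms, no
#' response). Conditions with no trials are dropped with a warning and
#' recorded in the \code{dropped} field. Nuisance regressors: motion
#' columns (constant columns removed), discrete-cosine drifts and an
#' intercept.
#'
#' @param events one run's \code{event_table} with an \code{outcome}
#'   column (hit/CR/FA/miss/none).
#' @param n_volumes,tr scan count and repetition time (s).
#' @param conditions named list mapping condition name to the outcomes it
#'   covers; default \code{hit}, \code{cr}, \code{other}.
#' @param motion optional \code{n_volumes x 6} motion parameter matrix.
#' @param cutoff_s high-pass cutoff (s).
#' @return list of class \code{design_matrix}: \code{X}, \code{names},
#'   \code{interest} (column indices of interest), \code{dropped},
#'   \code{n_volumes}, \code{tr}.
#' @export
build_condition_design <- function(events, n_volumes, tr,
                                   conditions = list(hit = "hit", cr = "CR",
                                                     other = c("FA", "miss", "none")),
                                   motion = NULL, cutoff_s = 128) {
  cols <- list(); dropped <- character(0)
  for (nm in names(conditions)) {
    sel <- events$outcome %in% conditions[[nm]]
    if (!any(sel)) {
      warning("condition '", nm, "' has no trials; column dropped")
      dropped <- c(dropped, nm)
      next
    }
    cols[[nm]] <- .convolved_regressor(events$onset[sel], n_volumes, tr)
  }
  X_int <- do.call(cbind, cols)
  mot <- .motion_columns(motion, n_volumes)
  dct <- highpass_basis(n_volumes, tr, cutoff_s)
  X <- cbind(X_int, mot, dct, intercept = 1)
  colnames(X) <- c(names(cols), colnames(mot), colnames(dct), "intercept")
  structure(list(X = X, names = colnames(X),
                 interest = seq_along(cols), dropped = dropped,
                 n_volumes = n_volumes, tr = tr),
            class = "design_matrix")
}

#' Condition-level design over all runs of a phase
#'
#' Like \code{\link{build_condition_design}} but for concatenated runs:
#' each condition of interest gets a single column spanning all runs,
#' while motion, drift and mean nuisance columns are per-session blocks.
#'
#' @inheritParams build_condition_design
#' @param events_list list of per-run \code{event_table}s.
#' @param motion_list optional list of per-run motion matrices.
#' @return a \code{design_matrix} with \code{length(events_list) *
#'   n_volumes} rows.
#' @export
condition_design_multirun <- function(events_list, n_volumes, tr,
                                      conditions = list(hit = "hit", cr = "CR",
                                                        other = c("FA", "miss", "none")),
                                      motion_list = NULL, cutoff_s = 128) {
  n_runs <- length(events_list)
  total_T <- n_runs * n_volumes
  cols <- list(); dropped <- character(0)
  for (nm in names(conditions)) {
    col <- numeric(total_T)
    n_events <- 0L
    for (r in seq_len(n_runs)) {
      ev <- events_list[[r]]
      sel <- ev$outcome %in% conditions[[nm]]
      n_events <- n_events + sum(sel)
      if (any(sel)) {
        rows <- (r - 1L) * n_volumes + seq_len(n_volumes)
        col[rows] <- .convolved_regressor(ev$onset[sel], n_volumes, tr)
      }
    }
    if (n_events == 0L) {
      warning("condition '", nm, "' has no trials; column dropped")
      dropped <- c(dropped, nm)
    } else cols[[nm]] <- col
  }
  X_int <- do.call(cbind, cols)
  nuis <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    mot <- .motion_columns(if (is.null(motion_list)) NULL else motion_list[[r]],
                           n_volumes)
    dct <- highpass_basis(n_volumes, tr, cutoff_s)
    nb <- cbind(mot, dct, mean = 1)
    colnames(nb) <- paste0("run", r, "_", c(colnames(mot), colnames(dct), "mean"))
    nuis[[r]] <- nb
  }
  n_nuis <- vapply(nuis, ncol, 0L)
  X_nu <- matrix(0, total_T, sum(n_nuis))
  col0 <- 0L; nm_nu <- character(0)
  for (r in seq_len(n_runs)) {
    rows <- (r - 1L) * n_volumes + seq_len(n_volumes)
    X_nu[rows, col0 + seq_len(n_nuis[r])] <- nuis[[r]]
    nm_nu <- c(nm_nu, colnames(nuis[[r]]))
    col0 <- col0 + n_nuis[r]
  }
  X <- cbind(X_int, X_nu)
  colnames(X) <- c(names(cols), nm_nu)
  structure(list(X = X, names = colnames(X), interest = seq_along(cols),
                 dropped = dropped, n_volumes = n_volumes, tr = tr),
            class = "design_matrix")
}

#' Single-trial (least-squares-all) design over all runs of a phase
#'
#' One regressor per trial across the concatenated runs of a phase, plus
#' per-session nuisance blocks: motion (when non-constant), discrete-cosine
#' drifts and session-mean columns. This is the least-squares-all scheme:
#' every trial is estimated in one joint model.
#'
#' @param events_list list of per-run \code{event_table}s (one phase).
#' @param n_volumes,tr per-run scan count and repetition time.
#' @param motion_list optional list of per-run motion matrices.
#' @param cutoff_s high-pass cutoff (s).
#' @return a \code{design_matrix} whose \code{X} has
#'   \code{length(events_list) * n_volumes} rows; trial columns are named
#'   \code{trial_<run>_<index>} and listed in \code{interest};
#'   \code{$trials} holds the row-bound event metadata in column order.
#' @export
single_trial_design <- function(events_list, n_volumes, tr,
                                motion_list = NULL, cutoff_s = 128) {
  n_runs <- length(events_list)
  ids <- unlist(lapply(events_list, function(e)
    paste(e$run[1], e$trial, sep = "_")))
  if (anyDuplicated(ids)) stop("duplicate trial ids across runs")
  n_trials <- vapply(events_list, nrow, 0L)
  total_T <- n_runs * n_volumes

  trial_blocks <- vector("list", n_runs)
  nuis_blocks <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    ev <- events_list[[r]]
    tm <- vapply(ev$onset, .convolved_regressor, numeric(n_volumes),
                 n_volumes = n_volumes, tr = tr)
    trial_blocks[[r]] <- tm
    mot <- .motion_columns(if (is.null(motion_list)) NULL else motion_list[[r]],
                           n_volumes)
    dct <- highpass_basis(n_volumes, tr, cutoff_s)
    nb <- cbind(mot, dct, mean = 1)
    colnames(nb) <- paste0("run", r, "_", c(colnames(mot), colnames(dct), "mean"))
    nuis_blocks[[r]] <- nb
  }

  X_tr <- matrix(0, total_T, sum(n_trials))
  col0 <- 0L
  for (r in seq_len(n_runs)) {
    rows <- (r - 1L) * n_volumes + seq_len(n_volumes)
    X_tr[rows, col0 + seq_len(n_trials[r])] <- trial_blocks[[r]]
    col0 <- col0 + n_trials[r]
  }
  colnames(X_tr) <- paste0("trial_", ids)

  n_nuis <- vapply(nuis_blocks, ncol, 0L)
  X_nu <- matrix(0, total_T, sum(n_nuis))
  col0 <- 0L; nm <- character(0)
  for (r in seq_len(n_runs)) {
    rows <- (r - 1L) * n_volumes + seq_len(n_volumes)
    X_nu[rows, col0 + seq_len(n_nuis[r])] <- nuis_blocks[[r]]
    nm <- c(nm, colnames(nuis_blocks[[r]]))
    col0 <- col0 + n_nuis[r]
  }
  colnames(X_nu) <- nm

  X <- cbind(X_tr, X_nu)
  meta <- do.call(rbind, events_list)
  structure(list(X = X, names = colnames(X),
                 interest = seq_len(sum(n_trials)), dropped = character(0),
                 n_volumes = n_volumes, tr = tr, trials = meta),
            class = "design_matrix")
}

# pooled lag-1 autocorrelation of residuals (internal)
.pooled_rho <- function(E, runs) {
  num <- 0; den <- 0
  for (r in unique(runs)) {
    Er <- E[runs == r, , drop = FALSE]
    n <- nrow(Er)
    num <- num + sum(Er[-1, ] * Er[-n, ])
    den <- den + sum(Er^2)
  }
  num / den
}

#' Fit a voxelwise general linear model
#'
#' Ordinary least squares per voxel; optionally a single pooled AR(1)
#' coefficient is estimated from the OLS residuals' lag-1 autocorrelation,
#' both sides are prewhitened and the model refit (a documented
#' simplification of full restricted maximum likelihood).
#'
#' @param Y data: either a \code{time x voxel} matrix or a 4D array (with a
#'   \code{mask} \code{\link{roi_mask}} selecting voxels); for multi-run
#'   designs, runs are concatenated in time.
#' @param design a \code{design_matrix}.
#' @param whitening \code{"none"} (default) or \code{"ar1"}.
#' @param mask optional \code{roi_mask} when \code{Y} is a 4D array.
#' @return list of class \code{glm_fit}: \code{beta}
#'   (regressor x voxel), \code{sigma2}, \code{df}, \code{rho},
#'   \code{design}, \code{mask}, \code{mean_signal} (per-voxel mean).
#' @export
fit_glm <- function(Y, design, whitening = c("none", "ar1"), mask = NULL) {
  whitening <- match.arg(whitening)
  if (is.array(Y) && length(dim(Y)) == 4L) {
    stopifnot(!is.null(mask))
    d <- dim(Y)
    Y <- t(matrix(Y, prod(d[1:3]), d[4])[mask$idx, , drop = FALSE])
  }
  X <- design$X
  stopifnot(nrow(Y) == nrow(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, Y)
  resid <- Y - X %*% beta
  df <- nrow(Y) - qrX$rank
  rho <- NA_real_
  if (whitening == "ar1") {
    n_runs <- nrow(Y) / design$n_volumes
    runs <- rep(seq_len(n_runs), each = design$n_volumes)
    rho <- .pooled_rho(resid, runs)
    W_rows <- function(M) {
      out <- M
      for (r in unique(runs)) {
        sel <- which(runs == r)
        Mr <- M[sel, , drop = FALSE]
        out[sel[1], ] <- sqrt(1 - rho^2) * Mr[1, ]
        out[sel[-1], ] <- Mr[-1, , drop = FALSE] -
          rho * Mr[-length(sel), , drop = FALSE]
      }
      out
    }
    Xw <- W_rows(X); Yw <- W_rows(Y)
    qrX <- qr(Xw)
    beta <- qr.coef(qrX, Yw)
    resid <- Yw - Xw %*% beta
    df <- nrow(Yw) - qrX$rank
  }
  sigma2 <- colSums(resid^2) / df
  structure(list(beta = beta, sigma2 = sigma2, df = df, rho = rho,
                 design = design, mask = mask,
                 mean_signal = colMeans(Y)),
            class = "glm_fit")
}

#' Extract single-trial betas as a beta stack
#'
#' @param fit a \code{glm_fit} from a \code{\link{single_trial_design}}.
#' @return list of class \code{beta_stack}: \code{betas}
#'   (trial x voxel), \code{trials} (metadata), \code{mask}.
#' @export
trial_betas <- function(fit) {
  stopifnot(!is.null(fit$design$trials))
  B <- t(fit$beta[fit$design$interest, , drop = FALSE])
  structure(list(betas = t(B), trials = fit$design$trials, mask = fit$mask),
            class = "beta_stack")
}

#' Scale betas to percent signal change
#'
#' SPM-style convention: \code{100 * beta * peak(unit-event regressor) /
#' mean signal}, where the peak is that of an HRF-convolved single event
#' evaluated on the fine microtime grid (for delta events this is the
#' kernel peak, 1 by construction), so a planted amplitude of 1\% of the
#' mean signal is reported as approximately 1.
#'
#' @param fit a \code{glm_fit}.
#' @param regressor column name or index of the regressor of interest.
#' @return numeric vector per voxel; voxels with non-positive mean signal
#'   are \code{NA}.
#' @export
percent_signal_change <- function(fit, regressor) {
  if (is.character(regressor)) regressor <- match(regressor, fit$design$names)
  stopifnot(!is.na(regressor))
  peak <- max(.hrf_kernel(0.1))
  out <- 100 * fit$beta[regressor, ] * peak / fit$mean_signal
  out[fit$mean_signal <= 0] <- NA_real_
  out
}

#' Voxelwise contrast of regression coefficients
#'
#' @param fit a \code{glm_fit}.
#' @param weights contrast weights over the regressors of interest
#'   (length \code{length(fit$design$interest)}).
#' @return numeric vector, one value per voxel.
#' @export
contrast_map <- function(fit, weights) {
  idx <- fit$design$interest
  stopifnot(length(weights) == length(idx))
  drop(crossprod(fit$beta[idx, , drop = FALSE], weights))
}

#' Gaussian spatial smoothing of 4D data
#'
#' Separable Gaussian kernel specified by its full width at half maximum in
#' mm; each volume is smoothed independently with zero-padding at the
#' edges (kernel renormalised inside the volume).
#'
#' @param x 4D array (x, y, z, t) or 3D array.
#' @param fwhm_mm full width at half maximum in mm (scalar).
#' @param voxel_mm voxel size in mm (length 3 or scalar).
#' @return array of the same shape.
#' @export
smooth_volumes <- function(x, fwhm_mm, voxel_mm = 3) {
  if (fwhm_mm <= 0) return(x)
  voxel_mm <- rep_len(voxel_mm, 3L)
  dims <- dim(x)
  is3d <- length(dims) == 3L
  if (is3d) { x <- array(x, c(dims, 1L)); dims <- dim(x) }
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  # per-axis banded smoothing matrices, rows renormalised at the edges
  smat <- function(n, s) {
    r <- max(1L, ceiling(3 * s))
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    K <- exp(-d^2 / (2 * s^2))
    K[d > r] <- 0
    K / rowSums(K)
  }
  Kx <- smat(dims[1], sigma_vox[1])
  Ky <- smat(dims[2], sigma_vox[2])
  Kz <- smat(dims[3], sigma_vox[3])
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]; nt <- dims[4]
  # x axis: one multiply over all volumes at once
  m <- Kx %*% matrix(x, nx, ny * nz * nt)
  # y axis
  a <- aperm(array(m, dims), c(2, 1, 3, 4))
  a <- Ky %*% matrix(a, ny, nx * nz * nt)
  a <- aperm(array(a, c(ny, nx, nz, nt)), c(2, 1, 3, 4))
  # z axis
  a <- aperm(a, c(3, 1, 2, 4))
  a <- Kz %*% matrix(a, nz, nx * ny * nt)
  out <- aperm(array(a, c(nz, nx, ny, nt)), c(2, 3, 1, 4))
  if (is3d) out <- array(out, dims[1:3])
  out
}
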