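#' ROI-mean beta series
#'
#' Per-trial spatial mean of single-trial betas over the voxels of an ROI
#' (the standard beta-series reduction, e.g. a 19-voxel 5 mm hippocampal
#' seed sphere). Trials whose ROI voxels are all missing become NA.
#'
#' @param stack a \code{beta_stack}.
#' @param roi an \code{\link{roi_mask}} within the stack's mask.
#' @return list of class \code{beta_series}: \code{values} (one scalar per
#'   trial), \code{trials} (metadata), \code{roi} (name).
#' @export
roi_beta_series <- function(stack, roi) {
  cols <- match(roi$idx, stack$mask$idx)
  if (anyNA(cols)) stop("ROI extends outside the beta stack's mask")
  if (length(cols) == 0L) stop("empty ROI")
  v <- rowMeans(stack$betas[, cols, drop = FALSE], na.rm = TRUE)
  v[!is.finite(v)] <- NA_real_
  structure(list(values = v, trials = stack$trials, roi = roi$name),
            class = "beta_series")
}

#' Beta-series connectivity within one trial type
#'
#' Pearson correlation between a seed and a target beta series computed
#' across the trials of a single outcome (hit or CR) only. Falls back to
#' NA with a warning when fewer than \code{min_trials} usable trials are
#' available.
#'
#' @param seed,target \code{beta_series} objects over the same trials.
#' @param outcome trial type to condition on (\code{"hit"} or \code{"CR"}).
#' @param min_trials minimum usable trials (default 10).
#' @return list: \code{r}, \code{z} (Fisher), \code{n_trials},
#'   \code{outcome}.
#' @export
condition_connectivity <- function(seed, target, outcome, min_trials = 10L) {
  stopifnot(length(seed$values) == length(target$values))
  sel <- seed$trials$outcome == outcome &
    !is.na(seed$values) & !is.na(target$values)
  n <- sum(sel)
  if (n < max(3L, min_trials)) {
    warning("only ", n, " usable '", outcome, "' trials (minimum ",
            min_trials, "); connectivity set to NA")
    return(list(r = NA_real_, z = NA_real_, n_trials = n, outcome = outcome))
  }
  r <- cor(seed$values[sel], target$values[sel])
  list(r = r, z = fisher_z(r), n_trials = n, outcome = outcome)
}

#' Whole-brain seed-to-voxel connectivity map
#'
#' Fisher-z of the correlation between the seed beta series and every
#' in-mask voxel's single-trial beta series, within one trial type.
#'
#' @param seed a \code{beta_series}.
#' @param stack a \code{beta_stack} over the brain mask.
#' @param outcome trial type (\code{"hit"} or \code{"CR"}).
#' @param brain_mask optional \code{\link{roi_mask}} restricting voxels
#'   (defaults to the stack's mask).
#' @param min_trials minimum usable trials.
#' @return numeric vector of z values, one per voxel of the mask, with the
#'   mask attached as attribute \code{"mask"}.
#' @export
seed_to_voxel <- function(seed, stack, outcome, brain_mask = NULL,
                          min_trials = 10L) {
  if (is.null(brain_mask)) brain_mask <- stack$mask
  cols <- match(brain_mask$idx, stack$mask$idx)
  if (anyNA(cols)) stop("brain mask extends outside the beta stack's mask")
  sel <- seed$trials$outcome == outcome & !is.na(seed$values)
  n <- sum(sel)
  if (n < max(3L, min_trials))
    stop("only ", n, " usable '", outcome, "' trials (minimum ", min_trials, ")")
  r <- suppressWarnings(
    cor(seed$values[sel], stack$betas[sel, cols, drop = FALSE]))
  z <- suppressWarnings(fisher_z(drop(r)))
  attr(z, "mask") <- brain_mask
  attr(z, "n_trials") <- n
  z
}

#' Group-level connectivity ANOVAs per target region
#'
#' For each target ROI, a Group x TrialType (hit, CR) mixed ANOVA on the
#' Fisher-z connectivity values plus per-group paired t tests on
#' z(CR) - z(hit). Subjects missing either condition for a target are
#' dropped from that target's analysis with a message. Significance flags
#' use the Bonferroni-adjusted alpha across targets.
#'
#' @param results data.frame, one row per subject x target x condition:
#'   \code{subject}, \code{group}, \code{target}, \code{condition}
#'   (hit/CR), \code{z} (and optionally \code{r}).
#' @param targets targets to analyse (default all present).
#' @param alpha family-wise alpha before adjustment (default 0.05).
#' @return list: \code{anovas} (per-target \code{\link{mixed_anova}}
#'   tables with significance flags), \code{followups} (per group paired
#'   t), \code{alpha_adjusted}.
#' @export
connectivity_anova <- function(results, targets = NULL, alpha = 0.05) {
  stopifnot(all(c("subject", "group", "target", "condition", "z") %in%
                  names(results)))
  if (is.null(targets)) targets <- sort(unique(results$target))
  alpha_adj <- bonferroni_threshold(alpha, length(targets))
  anovas <- list(); followups <- list()
  for (tg in targets) {
    sub <- results[results$target == tg & !is.na(results$z), ]
    cnt <- table(sub$subject)
    complete <- names(cnt)[cnt == 2L]
    dropped <- setdiff(unique(sub$subject), complete)
    if (length(dropped))
      message("target ", tg, ": dropping subject(s) without both conditions: ",
              paste(dropped, collapse = ", "))
    sub <- sub[sub$subject %in% complete, ]
    an <- mixed_anova(data.frame(subject = sub$subject, group = sub$group,
                                 level = sub$condition, value = sub$z,
                                 stringsAsFactors = FALSE))
    an$significant <- !is.na(an$p) & an$p < alpha_adj
    anovas[[tg]] <- an
    fw <- do.call(rbind, lapply(unique(sub$group), function(g) {
      gs <- sub[sub$group == g, ]
      cr <- gs$z[gs$condition == "CR"][order(gs$subject[gs$condition == "CR"])]
      ht <- gs$z[gs$condition == "hit"][order(gs$subject[gs$condition == "hit"])]
      tt <- paired_t(cr, ht)
      data.frame(target = tg, group = g, mean_diff = tt$mean_diff, t = tt$t,
                 df = tt$df, p = tt$p, stringsAsFactors = FALSE)
    }))
    followups[[tg]] <- fw
  }
  list(anovas = anovas, followups = do.call(rbind, followups),
       alpha_adjusted = alpha_adj)
}
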