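#' Trial-by-trial pattern similarity matrix
#'
#' Pearson correlation between every pair of single-trial beta patterns
#' over the voxels of an ROI (use unsmoothed betas). Trials whose pattern
#' has zero variance across the ROI produce missing entries, with a
#' warning naming the trials.
#'
#' @param stack a \code{beta_stack} (see \code{\link{trial_betas}}):
#'   \code{$betas} is trial x voxel over some brain mask, with trial
#'   metadata in \code{$trials}.
#' @param roi an \code{\link{roi_mask}}; must be a subset of the stack's
#'   mask.
#' @return matrix (trial x trial) of correlations with the stack's trial
#'   metadata attached as attribute \code{"trials"}; diagonal is 1.
#' @export
similarity_matrix <- function(stack, roi) {
  cols <- match(roi$idx, stack$mask$idx)
  if (anyNA(cols)) stop("ROI extends outside the beta stack's mask")
  if (length(cols) < 2L) stop("need at least 2 voxels in the ROI")
  P <- stack$betas[, cols, drop = FALSE]           # trial x voxel
  sds <- apply(P, 1, sd)
  flat <- which(sds == 0 | is.na(sds))
  S <- suppressWarnings(cor(t(P)))
  if (length(flat)) {
    warning("zero-variance pattern for trial(s) ",
            paste(flat, collapse = ", "), "; entries set to NA")
    S[flat, ] <- NA_real_; S[, flat] <- NA_real_
  }
  diag(S) <- 1
  attr(S, "trials") <- stack$trials
  S
}

#' Write or read a full similarity matrix as CSV
#'
#' Trial ids (\code{run_trial}) are used as column headers; the trial
#' metadata needed to recompute level means (\code{run}, \code{picture},
#' \code{outcome}) is prepended as columns.
#'
#' @param S a similarity matrix with a \code{"trials"} attribute.
#' @param path output CSV path.
#' @export
write_similarity_csv <- function(S, path) {
  trials <- attr(S, "trials")
  stopifnot(!is.null(trials))
  ids <- paste(trials$run, trials$trial, sep = "_")
  df <- cbind(data.frame(trial_id = ids, run = trials$run,
                         picture = trials$picture,
                         outcome = trials$outcome,
                         stringsAsFactors = FALSE),
              as.data.frame(`colnames<-`(S, ids)))
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_similarity_csv
#' @return \code{read_similarity_csv} returns the matrix with the trial
#'   metadata reattached.
#' @export
read_similarity_csv <- function(path) {
  df <- read.delim(path, sep = ",", stringsAsFactors = FALSE,
                   check.names = FALSE)
  meta <- df[, 1:4]
  S <- as.matrix(df[, -(1:4)])
  dimnames(S) <- list(meta$trial_id, colnames(S))
  attr(S, "trials") <- data.frame(run = meta$run, trial = sub(".*_", "", meta$trial_id),
                                  picture = meta$picture, outcome = meta$outcome,
                                  stringsAsFactors = FALSE)
  S
}

#' Fisher r-to-z transform
#'
#' \code{z = artanh(r)}; correlations at or beyond +/-1 are clipped to
#' +/-(1 - 1e-7) with a warning so the transform stays finite.
#'
#' @param r numeric vector of correlations.
#' @return numeric vector of z values.
#' @export
fisher_z <- function(r) {
  out_of_range <- !is.na(r) & abs(r) >= 1
  if (any(out_of_range)) {
    warning(sum(out_of_range), " correlation(s) at |r| >= 1 clipped")
    r[out_of_range] <- sign(r[out_of_range]) * (1 - 1e-7)
  }
  atanh(r)
}

#' Mean pattern similarity by relatedness level
#'
#' Averages Fisher-z similarities over unordered across-run trial pairs at
#' each relatedness level (SE, SS, SC, DC), and derives the distinctiveness
#' difference scores between successive levels (exemplar = SE - SS,
#' subcategory = SS - SC, category = SC - DC). Within-run pairs and the
#' diagonal are excluded; missing entries are dropped with their counts
#' reported.
#'
#' @param S similarity matrix from \code{\link{similarity_matrix}} (or any
#'   square matrix with a \code{"trials"} attribute).
#' @param trials optional trial metadata overriding the attribute; needs
#'   columns \code{run} and \code{picture} (and \code{outcome} when
#'   filtering).
#' @param accuracy_filter \code{"all"} (default) or \code{"correct_only"}
#'   (restrict to trials whose \code{outcome} is hit or CR — the
#'   subsequently-correct robustness variant).
#' @param hierarchy a \code{\link{stimulus_hierarchy}}.
#' @return list of class \code{similarity_result}: \code{level_z} (named
#'   mean z at SE/SS/SC/DC), \code{scores} (exemplar, subcategory,
#'   category), \code{n_pairs}, \code{n_used} (non-missing pairs).
#' @export
level_means <- function(S, trials = NULL, accuracy_filter = c("all", "correct_only"),
                        hierarchy = stimulus_hierarchy()) {
  accuracy_filter <- match.arg(accuracy_filter)
  if (is.null(trials)) trials <- attr(S, "trials")
  stopifnot(!is.null(trials), nrow(trials) == nrow(S),
            all(c("run", "picture") %in% names(trials)))
  keep <- rep(TRUE, nrow(S))
  if (accuracy_filter == "correct_only") {
    stopifnot("outcome" %in% names(trials))
    keep <- trials$outcome %in% c("hit", "CR")
  }
  n <- nrow(S)
  pair <- which(upper.tri(S), arr.ind = TRUE)
  i <- pair[, 1]; j <- pair[, 2]
  across <- trials$run[i] != trials$run[j] & keep[i] & keep[j]
  i <- i[across]; j <- j[across]
  lev <- relatedness_level(trials$picture[i], trials$picture[j], hierarchy)
  z <- fisher_z(S[cbind(i, j)])
  counts <- table(lev)
  if (any(counts == 0))
    stop("no across-run pairs at level(s): ",
         paste(names(counts)[counts == 0], collapse = ", "))
  level_z <- tapply(z, lev, mean, na.rm = TRUE)[relatedness_levels()]
  used <- tapply(!is.na(z), lev, sum)[relatedness_levels()]
  scores <- c(exemplar = unname(level_z["SE"] - level_z["SS"]),
              subcategory = unname(level_z["SS"] - level_z["SC"]),
              category = unname(level_z["SC"] - level_z["DC"]))
  structure(list(level_z = level_z, scores = scores,
                 n_pairs = as.integer(counts[relatedness_levels()]),
                 n_used = as.integer(used)),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat("Mean Fisher-z pattern similarity by relatedness level\n")
  print(round(x$level_z, 4))
  cat("Distinctiveness scores\n")
  print(round(x$scores, 4))
  invisible(x)
}

#' Group-level inference on pattern-similarity results
#'
#' Runs the Group x Level mixed ANOVA over the four level means, one-sample
#' t tests of each distinctiveness difference score against zero within
#' each group (two-sided p reported with the sign of the effect), and
#' between-group independent t tests at each level.
#'
#' @param results data.frame with one row per subject x level:
#'   \code{subject}, \code{group}, \code{level} (SE/SS/SC/DC),
#'   \code{value} (mean z); difference scores are recomputed from the
#'   level values.
#' @return list: \code{anova} (\code{\link{mixed_anova}} table),
#'   \code{score_tests} (group x score one-sample t results),
#'   \code{level_tests} (between-group t per level).
#' @export
group_rsa_stats <- function(results) {
  stopifnot(all(c("subject", "group", "level", "value") %in% names(results)))
  groups <- unique(results$group)
  stopifnot(length(groups) == 2L)
  for (g in groups)
    if (length(unique(results$subject[results$group == g])) < 2L)
      stop("need >= 2 subjects per group")
  results$level <- factor(results$level, levels = relatedness_levels())
  an <- mixed_anova(results)

  wide <- stats::reshape(results[, c("subject", "group", "level", "value")],
                         idvar = c("subject", "group"), timevar = "level",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide$exemplar <- wide$SE - wide$SS
  wide$subcategory <- wide$SS - wide$SC
  wide$category <- wide$SC - wide$DC

  score_tests <- do.call(rbind, lapply(groups, function(g) {
    sub <- wide[wide$group == g, ]
    do.call(rbind, lapply(c("exemplar", "subcategory", "category"), function(sc) {
      tt <- paired_t(sub[[sc]])
      data.frame(group = g, score = sc, mean = tt$mean_diff, t = tt$t,
                 df = tt$df, p = tt$p, stringsAsFactors = FALSE)
    }))
  }))

  level_tests <- do.call(rbind, lapply(relatedness_levels(), function(l) {
    a <- wide[[l]][wide$group == groups[1]]
    b <- wide[[l]][wide$group == groups[2]]
    tt <- independent_t(a, b)
    data.frame(level = l, group1 = groups[1], group2 = groups[2],
               mean1 = mean(a), mean2 = mean(b), t = tt$t, df = tt$df,
               p = tt$p, stringsAsFactors = FALSE)
  }))
  list(anova = an, score_tests = score_tests, level_tests = level_tests)
}
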