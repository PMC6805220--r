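#' Analysis options
#'
#' @param smoothing_fwhm_mm Gaussian smoothing applied before the
#'   univariate and connectivity models (default 8 mm); the
#'   representational-similarity path always uses unsmoothed data.
#' @param whitening \code{"none"} or \code{"ar1"} for the GLMs.
#' @param accuracy_filter \code{"all"} or \code{"correct_only"} for the
#'   encoding similarity analysis.
#' @param min_trials minimum trials per condition for connectivity.
#' @param alpha base alpha for the ROI ANOVA families.
#' @param seed_radius_mm participant-specific hippocampal seed radius.
#' @param targets connectivity target region names.
#' @return list of class \code{analysis_options}.
#' @export
analysis_options <- function(smoothing_fwhm_mm = 8, whitening = "none",
                             accuracy_filter = "all", min_trials = 10L,
                             alpha = 0.05, seed_radius_mm = 5,
                             targets = c("ANG", "DLPFC", "VLPFC")) {
  structure(list(smoothing_fwhm_mm = smoothing_fwhm_mm, whitening = whitening,
                 accuracy_filter = accuracy_filter, min_trials = min_trials,
                 alpha = alpha, seed_radius_mm = seed_radius_mm,
                 targets = targets),
            class = "analysis_options")
}

# time x voxel matrix over mask from a list of 4D runs; runs may already
# be time x voxel matrices over the same mask (fast path, no smoothing)
.concat_runs <- function(runs, mask, fwhm = 0, voxel_mm = 3) {
  mats <- lapply(runs, function(a) {
    if (length(dim(a)) == 2L) {
      rmask <- attr(a, "mask")
      stopifnot(!is.null(rmask))
      if (fwhm > 0) stop("smoothing requires full 4D runs, not masked matrices")
      return(a[, match(mask$idx, rmask$idx), drop = FALSE])
    }
    if (fwhm > 0) a <- smooth_volumes(a, fwhm, voxel_mm)
    d <- dim(a)
    t(matrix(a, prod(d[1:3]), d[4])[mask$idx, , drop = FALSE])
  })
  do.call(rbind, mats)
}

#' Analyse one subject end-to-end
#'
#' Runs the full single-subject chain on in-memory data: behavioural
#' scoring; condition-level GLM on smoothed test runs with percent-signal-
#' change extraction per region; participant-specific hippocampal seed
#' from the hit > CR contrast; single-trial (least-squares-all) GLMs for
#' the test phase (smoothed; beta-series connectivity) and study phase
#' (unsmoothed; representational similarity over the VTC).
#'
#' @param runs list of six 4D arrays (runs in order).
#' @param events full \code{event_table} covering all runs.
#' @param regions named region list; must include \code{VTC},
#'   \code{HIPP} and the connectivity targets.
#' @param grid a \code{\link{volume_grid}}.
#' @param tr repetition time (s).
#' @param options an \code{\link{analysis_options}} list.
#' @param brain_mask optional \code{\link{roi_mask}}; defaults to the
#'   union of the supplied regions.
#' @return list: \code{behavior}, \code{psc} (region x condition),
#'   \code{rsa} (a \code{similarity_result}), \code{connectivity}
#'   (target x condition r/z), \code{seed} (seed spec).
#' @export
analyze_subject <- function(runs, events, regions, grid, tr = 2,
                            options = analysis_options(),
                            brain_mask = NULL) {
  if (is.null(brain_mask))
    brain_mask <- roi_union(regions[setdiff(names(regions), "HIPP_PEAK")],
                            name = "brain")
  n_volumes <- if (length(dim(runs[[1]])) == 2L) nrow(runs[[1]])
               else dim(runs[[1]])[4]
  study_runs <- sort(unique(events$run[events$phase == "study"]))
  test_runs <- sort(unique(events$run[events$phase == "test"]))
  ev_by_run <- split(events, events$run)

  behavior <- score_behavior(events)

  # ---- univariate: condition GLM on smoothed test runs --------------------
  Y_test_sm <- .concat_runs(runs[test_runs], brain_mask,
                            fwhm = options$smoothing_fwhm_mm,
                            voxel_mm = grid$voxel_mm)
  des_cond <- condition_design_multirun(ev_by_run[as.character(test_runs)],
                                        n_volumes, tr)
  fit_cond <- fit_glm(Y_test_sm, des_cond, whitening = options$whitening)
  psc <- lapply(c(hit = "hit", cr = "cr"), function(cn) {
    if (cn %in% fit_cond$design$names) percent_signal_change(fit_cond, cn)
    else rep(NA_real_, ncol(fit_cond$beta))
  })
  roi_names <- setdiff(names(regions), c("VTC", "HIPP_PEAK"))
  psc_tab <- do.call(rbind, lapply(roi_names, function(nm) {
    cols <- match(regions[[nm]]$idx, brain_mask$idx)
    data.frame(region = nm,
               hit = mean(psc$hit[cols], na.rm = TRUE),
               cr = mean(psc$cr[cols], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))

  # ---- participant-specific hippocampal seed ------------------------------
  con <- contrast_map(fit_cond, c(1, -1, 0)[seq_along(fit_cond$design$interest)])
  full <- rep(NA_real_, n_voxels(grid))
  full[brain_mask$idx] <- con
  seed <- participant_seed(full, regions$HIPP,
                           radius_mm = options$seed_radius_mm)
  seed_roi <- roi_mask(intersect(seed$roi$idx, brain_mask$idx), grid,
                       name = seed$roi$name)

  # ---- single-trial GLM, test phase (smoothed) -> connectivity ------------
  des_test <- single_trial_design(ev_by_run[as.character(test_runs)],
                                  n_volumes, tr)
  fit_test <- fit_glm(Y_test_sm, des_test, whitening = options$whitening)
  stack_test <- trial_betas(fit_test)
  stack_test$mask <- brain_mask
  seed_series <- roi_beta_series(stack_test, seed_roi)
  conn <- do.call(rbind, lapply(options$targets, function(tg) {
    ts <- roi_beta_series(stack_test, regions[[tg]])
    do.call(rbind, lapply(c("hit", "CR"), function(oc) {
      cc <- condition_connectivity(seed_series, ts, oc,
                                   min_trials = options$min_trials)
      data.frame(target = tg, condition = oc, r = cc$r, z = cc$z,
                 n_trials = cc$n_trials, stringsAsFactors = FALSE)
    }))
  }))

  # ---- single-trial GLM, study phase (unsmoothed) -> RSA ------------------
  rm(Y_test_sm)
  Y_study <- .concat_runs(runs[study_runs], brain_mask, fwhm = 0)
  des_study <- single_trial_design(ev_by_run[as.character(study_runs)],
                                   n_volumes, tr)
  fit_study <- fit_glm(Y_study, des_study, whitening = options$whitening)
  stack_study <- trial_betas(fit_study)
  stack_study$mask <- brain_mask
  S <- similarity_matrix(stack_study, regions$VTC)
  rsa <- level_means(S, accuracy_filter = options$accuracy_filter)

  list(behavior = behavior, psc = psc_tab, rsa = rsa, connectivity = conn,
       seed = seed$spec)
}

#' Simulate a cohort dataset from a configuration
#'
#' Thin wrapper over \code{\link{simulate_cohort}} driven by a
#' configuration list (or JSON file path) with fields \code{out_dir},
#' \code{n_per_group}, \code{seed}, \code{grid_shape}, \code{voxel_mm},
#' \code{groups} (preset names). Missing fields use the stated-world
#' defaults.
#'
#' @param config list or path to a JSON file.
#' @return the dataset directory, invisibly.
#' @export
run_simulation <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  grid <- volume_grid(config$grid_shape %||% c(30, 36, 24),
                      config$voxel_mm %||% 3)
  groups <- config$groups %||% c("young", "old")
  presets <- lapply(setNames(nm = groups), cohort_presets)
  simulate_cohort(config$out_dir,
                  n_per_group = config$n_per_group %||% 20L,
                  presets = presets, grid = grid,
                  regions = default_regions(grid),
                  seed = config$seed %||% 1L,
                  tr = config$tr %||% 2,
                  n_volumes = config$n_volumes %||% 205L,
                  n_pairs = config$n_pairs %||% 192L,
                  n_lists = config$n_lists %||% 3L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# read one subject's runs + events from a dataset tree (internal)
.load_subject <- function(dir, sid) {
  fdir <- file.path(dir, sid, "func")
  bolds <- sort(list.files(fdir, "_bold\\.nii(\\.gz)?$", full.names = TRUE))
  evs <- sort(list.files(fdir, "_events\\.tsv$", full.names = TRUE))
  runs <- lapply(bolds, function(f) read_nifti(f)$data)
  events <- do.call(rbind, lapply(seq_along(evs), function(r)
    read_events_tsv(evs[r], run = r)))
  nii <- read_nifti(bolds[1])
  list(runs = runs, events = events, grid = nii$grid, tr = nii$tr)
}

#' Structural validation of a dataset tree
#'
#' Checks run counts, per-run trial counts, grid agreement between runs
#' and masks, and the presence of the required region masks.
#'
#' @param dir dataset directory from \code{\link{simulate_cohort}} (or an
#'   equivalent user-supplied tree).
#' @param expect_runs,expect_trials expected counts (6 runs, 64 trials).
#' @return list with \code{ok} (logical) and \code{failures} (character
#'   vector of named failures, empty when valid).
#' @export
validate_dataset <- function(dir, expect_runs = 6L, expect_trials = 64L) {
  failures <- character(0)
  subs <- sort(list.files(dir, "^sub-", include.dirs = TRUE))
  if (!length(subs)) failures <- c(failures, "no sub-* directories")
  mask_dir <- file.path(dir, "masks")
  need <- c("VTC", "HIPP", "ANG", "DLPFC", "VLPFC")
  mask_files <- file.path(mask_dir, paste0(need, ".nii"))
  missing_masks <- need[!file.exists(mask_files)]
  if (length(missing_masks))
    failures <- c(failures, paste0("missing mask: ",
                                   paste(missing_masks, collapse = ", ")))
  ref_grid <- NULL
  if (!length(missing_masks)) ref_grid <- read_nifti(mask_files[1])$grid
  for (s in subs) {
    fdir <- file.path(dir, s, "func")
    bolds <- list.files(fdir, "_bold\\.nii(\\.gz)?$", full.names = TRUE)
    evs <- list.files(fdir, "_events\\.tsv$", full.names = TRUE)
    if (length(bolds) != expect_runs)
      failures <- c(failures, sprintf("%s: %d runs (expected %d)", s,
                                      length(bolds), expect_runs))
    if (length(evs) != expect_runs)
      failures <- c(failures, sprintf("%s: %d event files (expected %d)", s,
                                      length(evs), expect_runs))
    for (f in evs) {
      n <- nrow(read.delim(f))
      if (n != expect_trials)
        failures <- c(failures, sprintf("%s: %d trials in %s (expected %d)",
                                        s, n, basename(f), expect_trials))
    }
    if (length(bolds) && !is.null(ref_grid)) {
      g <- read_nifti(bolds[1])$grid
      if (!grids_equal(g, ref_grid))
        failures <- c(failures, sprintf("%s: run grid differs from masks", s))
    }
  }
  list(ok = length(failures) == 0L, failures = failures)
}

#' Run the full group analysis over a dataset tree
#'
#' For every subject: behaviour, region percent signal change,
#' encoding-phase similarity and hippocampal beta-series connectivity
#' (\code{\link{analyze_subject}}); then group statistics: a Table-1-style
#' behavioural summary with independent t tests, the Group x Level
#' similarity ANOVA with distinctiveness-score tests, per-region
#' Group x TrialType activation ANOVAs (Bonferroni alpha 0.05/4) and
#' per-target connectivity ANOVAs (alpha 0.05/3). Results are written as
#' tidy CSV files plus PNG figure analogues and a provenance JSON.
#'
#' @param dataset_dir dataset tree (see \code{\link{simulate_cohort}}).
#' @param out_dir report directory (created).
#' @param options an \code{\link{analysis_options}} list.
#' @param write_plots emit PNG figures (default TRUE).
#' @return (invisibly) list with the aggregated tables:
#'   \code{behavior}, \code{behavior_tests}, \code{rsa_levels},
#'   \code{rsa_stats}, \code{psc}, \code{psc_anovas}, \code{connectivity},
#'   \code{connectivity_stats}, \code{failed_subjects}.
#' @export
run_analysis <- function(dataset_dir, out_dir,
                         options = analysis_options(), write_plots = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- jsonlite::read_json(file.path(dataset_dir, "ground_truth.json"),
                               simplifyVector = FALSE)
  subs <- sort(names(truth$subjects))
  mask_dir <- file.path(dataset_dir, "masks")
  mask_files <- list.files(mask_dir, "\\.nii(\\.gz)?$", full.names = TRUE)
  grid <- read_nifti(mask_files[1])$grid
  regions <- lapply(mask_files, function(f) {
    nm <- sub("\\.nii(\\.gz)?$", "", basename(f))
    roi_mask(array(read_nifti(f)$data > 0.5, grid$shape), grid, name = nm,
             provenance = list(file = f))
  })
  names(regions) <- vapply(regions, `[[`, "", "name")

  per_subj <- list(); failed <- character(0)
  for (s in subs) {
    res <- tryCatch({
      d <- .load_subject(dataset_dir, s)
      analyze_subject(d$runs, d$events, regions, grid,
                      tr = if (d$tr > 0) d$tr else 2, options = options)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("subject ", s, " failed and was quarantined: ",
              conditionMessage(res))
      failed <- c(failed, s)
    } else {
      res$group <- truth$subjects[[s]]$group
      per_subj[[s]] <- res
    }
  }
  if (!length(per_subj)) stop("no subject completed the analysis")
  agg <- aggregate_results(per_subj, alpha = options$alpha)
  agg$failed_subjects <- failed

  write_csv <- function(df, name)
    write.table(df, file.path(out_dir, name), sep = ",", row.names = FALSE,
                quote = FALSE)
  write_csv(agg$behavior, "behavior.csv")
  write_csv(agg$behavior_tests, "behavior_tests.csv")
  write_csv(agg$rsa_levels, "rsa_level_means.csv")
  write_csv(agg$rsa_stats$anova, "rsa_anova.csv")
  write_csv(agg$rsa_stats$score_tests, "rsa_score_tests.csv")
  write_csv(agg$rsa_stats$level_tests, "rsa_level_tests.csv")
  write_csv(agg$psc, "roi_psc.csv")
  write_csv(agg$psc_followups, "roi_followups.csv")
  write_csv(do.call(rbind, lapply(names(agg$psc_anovas), function(nm) {
    a <- agg$psc_anovas[[nm]]; a$region <- nm; a
  })), "roi_anovas.csv")
  write_csv(agg$connectivity, "connectivity.csv")
  write_csv(do.call(rbind, lapply(names(agg$connectivity_stats$anovas),
                                  function(nm) {
    a <- agg$connectivity_stats$anovas[[nm]]; a$target <- nm; a
  })), "connectivity_anovas.csv")
  write_csv(agg$connectivity_stats$followups, "connectivity_followups.csv")
  prov <- list(dataset = normalizePath(dataset_dir), options = unclass(options),
               dataset_seed = truth$seed,
               n_subjects = length(per_subj), failed = failed,
               package_version = as.character(utils::packageVersion("dediffr")))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (write_plots) .report_plots(agg, out_dir)
  invisible(agg)
}

#' Aggregate per-subject results into group tables and statistics
#'
#' @param per_subj named list of \code{\link{analyze_subject}} outputs,
#'   each with a \code{group} element attached.
#' @param alpha base alpha for the ANOVA families.
#' @return list of tidy tables and test results (see
#'   \code{\link{run_analysis}}).
#' @export
aggregate_results <- function(per_subj, alpha = 0.05) {
  subs <- names(per_subj)
  grp <- vapply(per_subj, `[[`, "", "group")

  groups <- unique(grp)
  # group-level inference needs at least two subjects in each group
  can_test <- length(groups) == 2L && all(table(grp) >= 2L)

  behavior <- do.call(rbind, lapply(subs, function(s) {
    b <- per_subj[[s]]$behavior
    data.frame(subject = s, group = grp[[s]], hits = b$hits, crs = b$crs,
               fas = b$fas, misses = b$misses, no_response = b$no_response,
               p_hit = b$p_hit, p_fa = b$p_fa,
               corrected_recognition = b$corrected_recognition,
               stringsAsFactors = FALSE)
  }))
  behavior_tests <- if (can_test) {
    do.call(rbind, lapply(c("hits", "crs", "corrected_recognition"),
                          function(mv) {
      a <- behavior[[mv]][behavior$group == groups[1]]
      b <- behavior[[mv]][behavior$group == groups[2]]
      tt <- independent_t(a, b)
      data.frame(measure = mv, group1 = groups[1], group2 = groups[2],
                 mean1 = mean(a), sd1 = sd(a), mean2 = mean(b), sd2 = sd(b),
                 t = tt$t, df = tt$df, p = tt$p, cohen_d = tt$cohen_d,
                 stringsAsFactors = FALSE)
    }))
  } else NULL

  rsa_levels <- do.call(rbind, lapply(subs, function(s) {
    lz <- per_subj[[s]]$rsa$level_z
    data.frame(subject = s, group = grp[[s]], level = names(lz),
               value = as.numeric(lz), stringsAsFactors = FALSE)
  }))
  rsa_stats <- if (can_test) group_rsa_stats(rsa_levels) else NULL

  psc <- do.call(rbind, lapply(subs, function(s) {
    p <- per_subj[[s]]$psc
    data.frame(subject = s, group = grp[[s]], region = p$region,
               hit = p$hit, cr = p$cr, stringsAsFactors = FALSE)
  }))
  psc_anovas <- NULL; psc_followups <- NULL
  if (can_test) {
    regions <- unique(psc$region)
    alpha_adj <- bonferroni_threshold(alpha, length(regions))
    psc_anovas <- lapply(setNames(nm = regions), function(rg) {
      sub <- psc[psc$region == rg, ]
      long <- rbind(
        data.frame(subject = sub$subject, group = sub$group, level = "hit",
                   value = sub$hit, stringsAsFactors = FALSE),
        data.frame(subject = sub$subject, group = sub$group, level = "CR",
                   value = sub$cr, stringsAsFactors = FALSE))
      an <- mixed_anova(long)
      an$significant <- !is.na(an$p) & an$p < alpha_adj
      an
    })
    psc_followups <- do.call(rbind, lapply(regions, function(rg) {
      sub <- psc[psc$region == rg, ]
      do.call(rbind, lapply(groups, function(g) {
        gs <- sub[sub$group == g, ]
        tt <- paired_t(gs$hit, gs$cr)
        data.frame(region = rg, group = g, contrast = "hit-CR",
                   mean_diff = tt$mean_diff, t = tt$t, df = tt$df, p = tt$p,
                   stringsAsFactors = FALSE)
      }))
    }))
  }

  connectivity <- do.call(rbind, lapply(subs, function(s) {
    cn <- per_subj[[s]]$connectivity
    data.frame(subject = s, group = grp[[s]], target = cn$target,
               condition = cn$condition, r = cn$r, z = cn$z,
               n_trials = cn$n_trials, stringsAsFactors = FALSE)
  }))
  connectivity_stats <- if (can_test)
    connectivity_anova(connectivity, alpha = alpha) else NULL

  list(behavior = behavior, behavior_tests = behavior_tests,
       rsa_levels = rsa_levels, rsa_stats = rsa_stats,
       psc = psc, psc_anovas = psc_anovas, psc_followups = psc_followups,
       connectivity = connectivity, connectivity_stats = connectivity_stats)
}

# figure analogues: level means, PSC bars, connectivity bars (internal)
.report_plots <- function(agg, out_dir) {
  grp_col <- function(g) ifelse(g == unique(agg$rsa_levels$group)[1],
                                "steelblue", "tomato")
  png_of <- function(name, expr) {
    grDevices::png(file.path(out_dir, name), width = 900, height = 600)
    on.exit(grDevices::dev.off())
    expr()
  }
  png_of("rsa_levels.png", function() {
    m <- tapply(agg$rsa_levels$value,
                list(agg$rsa_levels$group, agg$rsa_levels$level), mean)
    m <- m[, relatedness_levels(), drop = FALSE]
    graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                      col = grp_col(rownames(m)),
                      ylab = "mean Fisher-z similarity",
                      main = "Encoding pattern similarity by relatedness")
  })
  png_of("roi_psc.png", function() {
    d <- agg$psc
    m <- tapply(c(d$hit, d$cr),
                list(rep(c("hit", "CR"), each = nrow(d)),
                     paste(rep(d$group, 2), rep(d$region, 2))), mean)
    graphics::barplot(m, beside = TRUE, legend.text = rownames(m), las = 2,
                      ylab = "percent signal change",
                      main = "Retrieval activation by region")
  })
  png_of("connectivity.png", function() {
    d <- agg$connectivity
    m <- tapply(d$r, list(d$condition, paste(d$group, d$target)), mean,
                na.rm = TRUE)
    graphics::barplot(m, beside = TRUE, legend.text = rownames(m), las = 2,
                      ylab = "mean Pearson r",
                      main = "Hippocampal beta-series connectivity")
  })
  invisible(NULL)
}
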