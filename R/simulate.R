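#' Model components for the synthetic BOLD generator
#'
#' Constructors for the four generative model pieces used by
#' \code{\link{simulate_run}}:
#' \describe{
#'   \item{pattern_model}{representational geometry in the ventral temporal
#'     cortex: every trial's spatial pattern is a weighted sum of a shared
#'     baseline map, a category map, a subcategory map, an exemplar map and
#'     trial-unique noise, all unit-variance over VTC voxels. Expected
#'     pattern correlation is non-increasing from same-exemplar to
#'     different-category pairs whenever all weights are non-negative.}
#'   \item{activation_model}{mean response amplitude by (region, phase,
#'     outcome); \code{"*"} acts as a wildcard.}
#'   \item{connectivity_model}{trial-wise coupling: a latent scalar shared
#'     by the seed region (weight 1) and each target region (weight
#'     \code{kappa(target, outcome)}).}
#'   \item{noise_model}{white noise SD, AR(1) coefficient and a slow
#'     cosine drift (period beyond the 128 s high-pass cutoff so filtering
#'     removes it).}
#' }
#'
#' @param w_base,w_cat,w_sub,w_ex,w_trial non-negative pattern weights.
#' @return an object of the corresponding class.
#' @name generator_models
NULL

#' @rdname generator_models
#' @export
pattern_model <- function(w_base = 0, w_cat = 0, w_sub = 0, w_ex = 0,
                          w_trial = 0) {
  w <- c(base = w_base, cat = w_cat, sub = w_sub, ex = w_ex, trial = w_trial)
  if (any(w < 0)) stop("pattern weights must be >= 0")
  structure(as.list(w), class = "pattern_model")
}

#' @rdname generator_models
#' @param amplitudes data.frame with columns \code{region}, \code{phase},
#'   \code{outcome}, \code{amplitude}; \code{"*"} matches anything.
#' @export
activation_model <- function(amplitudes) {
  stopifnot(all(c("region", "phase", "outcome", "amplitude") %in%
                  names(amplitudes)),
            all(is.finite(amplitudes$amplitude)))
  structure(list(amplitudes = amplitudes), class = "activation_model")
}

#' @rdname generator_models
#' @param kappa data.frame with columns \code{target}, \code{outcome},
#'   \code{kappa} (>= 0); \code{seed} names the seed region;
#'   \code{latent_sd} scales the shared trial latent.
#' @param seed_region name of the seed region.
#' @param latent_sd SD of the shared per-trial latent.
#' @export
connectivity_model <- function(kappa = NULL, seed_region = "HIPP",
                               latent_sd = 0.5) {
  if (is.null(kappa))
    kappa <- data.frame(target = character(0), outcome = character(0),
                        kappa = numeric(0))
  stopifnot(all(kappa$kappa >= 0))
  structure(list(kappa = kappa, seed_region = seed_region,
                 latent_sd = latent_sd), class = "connectivity_model")
}

#' @rdname generator_models
#' @param white_sd marginal SD of the AR(1) noise.
#' @param ar1_rho AR(1) coefficient, |rho| < 1.
#' @param drift_amplitude,drift_period_s slow cosine drift (period must
#'   exceed the high-pass cutoff for the analysis to remove it).
#' @export
noise_model <- function(white_sd = 1, ar1_rho = 0.12, drift_amplitude = 2,
                        drift_period_s = 300) {
  stopifnot(abs(ar1_rho) < 1, white_sd >= 0)
  structure(list(white_sd = white_sd, ar1_rho = ar1_rho,
                 drift_amplitude = drift_amplitude,
                 drift_period_s = drift_period_s), class = "noise_model")
}

#' Closed-form expected pattern correlation by relatedness level
#'
#' With unit-variance independent component maps, the expected Pearson
#' correlation between two trials sharing components is the ratio of shared
#' to total pattern variance: for same-exemplar pairs
#' \deqn{E[r_{SE}] = (w_b^2 + w_c^2 + w_s^2 + w_e^2) /
#'       (w_b^2 + w_c^2 + w_s^2 + w_e^2 + w_t^2),}
#' dropping the terms of unshared components for SS, SC and DC pairs.
#'
#' @param pm a \code{\link{pattern_model}}.
#' @return named numeric vector with elements SE, SS, SC, DC.
#' @examples
#' expected_similarity(pattern_model(0, 1, 1, 1, 1))  # 3/4, 2/4, 1/4, 0
#' @export
expected_similarity <- function(pm) {
  stopifnot(inherits(pm, "pattern_model"))
  w2 <- c(pm$base, pm$cat, pm$sub, pm$ex, pm$trial)^2
  tot <- sum(w2)
  if (tot == 0) stop("all pattern weights are zero; correlation undefined")
  c(SE = sum(w2[1:4]), SS = sum(w2[1:3]), SC = sum(w2[1:2]),
    DC = w2[1]) / tot
}

#' Group parameter presets for the synthetic cohort
#'
#' The presets encode the stated world the generator emulates:
#' \itemize{
#'   \item \code{young}: graded representational structure (expected level
#'     correlations about .41/.36/.27/.05), hippocampal and angular-gyrus
#'     hit > CR activation, DLPFC CR > hit, and hippocampal-VLPFC coupling
#'     stronger during CRs than hits.
#'   \item \code{old}: dedifferentiated geometry (lower exemplar and
#'     subcategory weights, higher shared baseline: about
#'     .32/.32/.30/.14), the same hit > CR effects in HIPP/ANG, a flat
#'     DLPFC, flat hippocampal coupling across trial types (and a higher
#'     overall coupling level), and Table-1 response rates.
#'   \item \code{null}: identical geometry and amplitudes across
#'     conditions and zero coupling — used for type-I-error calibration.
#' }
#' Behavioural hit/CR probabilities are the printed group mean counts over
#' 96 test trials of each status.
#'
#' @param group \code{"young"}, \code{"old"} or \code{"null"}.
#' @return list with elements \code{pattern}, \code{activation},
#'   \code{connectivity}, \code{noise}, \code{behavior} and the
#'   between-subject jitter SDs (\code{pattern_jitter_sd},
#'   \code{amp_jitter_sd}, \code{kappa_jitter_sd}, \code{trial_amp_sd}).
#' @export
cohort_presets <- function(group = c("young", "old", "null")) {
  group <- match.arg(group)
  base_act <- function(dlpfc_hit, dlpfc_cr) activation_model(data.frame(
    region = c("VTC", "HIPP", "HIPP", "HIPP_PEAK", "HIPP_PEAK",
               "ANG", "ANG", "DLPFC", "DLPFC", "VLPFC", "VLPFC", "*"),
    phase = c("study", rep("test", 10), "*"),
    outcome = c("*", "hit", "CR", "hit", "CR", "hit", "CR", "hit", "CR",
                "hit", "CR", "*"),
    amplitude = c(1.0, 1.2, 0.6, 2.6, 0.6, 1.2, 0.7, dlpfc_hit, dlpfc_cr,
                  0.8, 0.9, 0.5),
    stringsAsFactors = FALSE))
  kap <- function(vl_hit, vl_cr, flat) data.frame(
    target = c("VLPFC", "VLPFC", "DLPFC", "DLPFC", "ANG", "ANG"),
    outcome = c("hit", "CR", "hit", "CR", "hit", "CR"),
    kappa = c(vl_hit, vl_cr, rep(flat, 4)),
    stringsAsFactors = FALSE)
  common <- list(noise = noise_model(),
                 pattern_jitter_sd = 0.25, amp_jitter_sd = 0.25,
                 kappa_jitter_sd = 0.15, trial_amp_sd = 0.3)
  spec <- switch(group,
    young = list(
      pattern = pattern_model(0.30, 0.60, 0.40, 0.30, 1),
      activation = base_act(0.6, 1.1),
      connectivity = connectivity_model(kap(0.4, 1.0, 0.7)),
      behavior = list(p_hit = 85.05 / 96, p_cr = 89.60 / 96, p_none = 0,
                      p_hit_sd = 0.068, p_cr_sd = 0.043)),
    old = list(
      pattern = pattern_model(0.45, 0.49, 0.17, 0.07, 1),
      activation = base_act(0.85, 0.85),
      connectivity = connectivity_model(kap(0.9, 0.9, 0.9)),
      behavior = list(p_hit = 71.90 / 96, p_cr = 72.0 / 96, p_none = 0,
                      p_hit_sd = 0.098, p_cr_sd = 0.115)),
    null = list(
      pattern = pattern_model(0.45, 0, 0, 0, 1),
      activation = activation_model(data.frame(
        region = "*", phase = "*", outcome = "*", amplitude = 0.8,
        stringsAsFactors = FALSE)),
      connectivity = connectivity_model(),
      behavior = list(p_hit = 0.8, p_cr = 0.8, p_none = 0,
                      p_hit_sd = 0.05, p_cr_sd = 0.05)))
  c(spec, common, list(group = group))
}

#' Default simulated region layout
#'
#' Places toy analysis regions on a grid: a box-shaped ventral temporal
#' cortex (VTC), an anatomical hippocampus sphere (HIPP) with a smaller
#' peak subregion (HIPP_PEAK) where the retrieval-success signal is
#' strongest, and three cortical spheres (ANG, DLPFC, VLPFC). Positions
#' are fractions of the grid extent so the layout scales with grid size.
#'
#' @param grid a \code{\link{volume_grid}}.
#' @param cortical_radius_mm radius of the cortical target spheres
#'   (default 10, as for coordinate-based retrieval ROIs).
#' @param hipp_radius_mm anatomical hippocampus radius (default 8).
#' @return named list of \code{\link{roi_mask}} objects.
#' @export
default_regions <- function(grid, cortical_radius_mm = 10, hipp_radius_mm = 8) {
  ext <- grid$voxel_mm * grid$shape
  orig <- grid$affine[1:3, 4]
  at <- function(fr) orig + fr * ext
  vtc_lo <- mm_to_voxel(grid, at(c(0.25, 0.08, 0.10)))
  vtc_hi <- mm_to_voxel(grid, at(c(0.75, 0.30, 0.35)))
  box <- array(FALSE, grid$shape)
  box[(vtc_lo[1]:vtc_hi[1]) + 1L, (vtc_lo[2]:vtc_hi[2]) + 1L,
      (vtc_lo[3]:vtc_hi[3]) + 1L] <- TRUE
  list(
    VTC = roi_mask(box, grid, name = "VTC",
                   provenance = list(type = "box")),
    HIPP = sphere_roi(at(c(0.32, 0.55, 0.50)), hipp_radius_mm, grid, "HIPP"),
    HIPP_PEAK = sphere_roi(at(c(0.32, 0.55, 0.50)), hipp_radius_mm / 2.5,
                           grid, "HIPP_PEAK"),
    ANG = sphere_roi(at(c(0.75, 0.80, 0.55)), cortical_radius_mm, grid, "ANG"),
    DLPFC = sphere_roi(at(c(0.30, 0.85, 0.85)), cortical_radius_mm, grid,
                       "DLPFC"),
    VLPFC = sphere_roi(at(c(0.80, 0.45, 0.80)), cortical_radius_mm, grid,
                       "VLPFC"))
}

# amplitude lookup with "*" wildcards; first match wins (internal)
.amp_lookup <- function(act, region, phase, outcome) {
  a <- act$amplitudes
  hit <- (a$region == region | a$region == "*") &
    (a$phase == phase | a$phase == "*") &
    (a$outcome == outcome | a$outcome == "*")
  if (!any(hit)) return(0)
  a$amplitude[which(hit)[1]]
}

#' Draw subject-level generator state
#'
#' Component pattern maps are drawn once per subject (subject-unique
#' geometry, standard normal, then standardised to unit variance over VTC
#' voxels), and the pattern weights, region amplitudes and coupling
#' strengths receive multiplicative log-normal between-subject jitter.
#'
#' @param preset a \code{\link{cohort_presets}} list.
#' @param regions region list including \code{VTC}.
#' @param seed optional RNG seed.
#' @return list used by \code{\link{simulate_run}} to keep runs of one
#'   subject coherent.
#' @export
subject_params <- function(preset, regions, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- stimulus_hierarchy()
  nv <- roi_size(regions$VTC)
  std <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x
  maps <- list(
    base = std(rnorm(nv)),
    cat = lapply(setNames(nm = unique(h$category)), function(.) std(rnorm(nv))),
    sub = lapply(setNames(nm = unique(h$subcategory)), function(.) std(rnorm(nv))),
    ex = lapply(setNames(nm = h$exemplar), function(.) std(rnorm(nv))))
  jit <- function(x, s) x * exp(rnorm(length(x), 0, s))
  w <- preset$pattern
  w_j <- pattern_model(jit(w$base, preset$pattern_jitter_sd),
                       jit(w$cat, preset$pattern_jitter_sd),
                       jit(w$sub, preset$pattern_jitter_sd),
                       jit(w$ex, preset$pattern_jitter_sd),
                       w$trial)
  act <- preset$activation
  act$amplitudes$amplitude <- act$amplitudes$amplitude +
    rnorm(nrow(act$amplitudes), 0, preset$amp_jitter_sd)
  kap <- preset$connectivity
  if (nrow(kap$kappa)) kap$kappa$kappa <- jit(kap$kappa$kappa,
                                              preset$kappa_jitter_sd)
  list(maps = maps, pattern = w_j, activation = act, connectivity = kap,
       noise = preset$noise, trial_amp_sd = preset$trial_amp_sd,
       behavior = preset$behavior, group = preset$group)
}

# per-trial, per-voxel amplitude matrix for one run (internal)
.trial_amplitudes <- function(events, regions, params) {
  grid <- regions[[1]]$grid
  nvox <- n_voxels(grid)
  nt <- nrow(events)
  phase <- events$phase[1]
  A <- matrix(0, nt, nvox)
  outc <- events$outcome
  outc[is.na(outc)] <- "*"
  seed_name <- params$connectivity$seed_region
  kap_tab <- params$connectivity$kappa
  xi <- rnorm(nt, 0, params$connectivity$latent_sd)
  for (nm in names(regions)) {
    idx <- regions[[nm]]$idx
    base_amp <- vapply(outc, function(o)
      .amp_lookup(params$activation, nm, phase, o), 0)
    amp <- base_amp + rnorm(nt, 0, params$trial_amp_sd)
    if (phase == "test") {
      if (nm == seed_name || nm == paste0(seed_name, "_PEAK")) {
        amp <- amp + xi
      } else if (nrow(kap_tab)) {
        k <- vapply(outc, function(o) {
          row <- kap_tab$target == nm & kap_tab$outcome == o
          if (any(row)) kap_tab$kappa[which(row)[1]] else 0
        }, 0)
        amp <- amp + k * xi
      }
    }
    A[, idx] <- amp
  }
  # representational geometry inside VTC during encoding
  if (phase == "study") {
    w <- params$pattern; mp <- params$maps
    vtc <- regions$VTC$idx
    h <- stimulus_hierarchy()
    for (t in seq_len(nt)) {
      ex <- events$picture[t]
      sub <- h$subcategory[match(ex, h$exemplar)]
      cat <- h$category[match(ex, h$exemplar)]
      pat <- w$base * mp$base + w$cat * mp$cat[[cat]] +
        w$sub * mp$sub[[sub]] + w$ex * mp$ex[[ex]] +
        w$trial * rnorm(length(vtc))
      A[t, vtc] <- A[t, vtc] + pat
    }
  }
  A
}

#' Simulate one BOLD run
#'
#' Builds the run as baseline + sum over trials of (HRF-convolved
#' regressor x planted amplitude map) + slow drift + AR(1) noise. Trial
#' amplitude maps combine region/condition activation, trial-wise
#' hippocampal-cortical coupling (test phase), and the VTC
#' representational geometry (study phase).
#'
#' @param events one run's \code{event_table}; outcomes must be filled
#'   for test runs.
#' @param grid a \code{\link{volume_grid}}.
#' @param regions named region list (see \code{\link{default_regions}}).
#' @param params subject state from \code{\link{subject_params}}.
#' @param tr repetition time (s), default 2.
#' @param n_volumes usable scans per run, default 205.
#' @param baseline mean signal level (default 100).
#' @param seed optional RNG seed.
#' @param mask optional \code{\link{roi_mask}}: restrict the simulation to
#'   the mask's voxels and return a \code{time x voxel} matrix instead of
#'   a 4D array (a fast path for mask-level analyses without smoothing;
#'   statistically identical inside the mask since noise is independent
#'   across voxels).
#' @return 4D array (x, y, z, t) with the grid as attribute
#'   \code{"grid"}, or a \code{time x voxel} matrix when \code{mask} is
#'   given (mask attached as attribute \code{"mask"}).
#' @export
simulate_run <- function(events, grid, regions, params, tr = 2,
                         n_volumes = 205, baseline = 100, seed = NULL,
                         mask = NULL) {
  if (!is.null(seed)) set.seed(seed)
  run_len <- n_volumes * tr
  if (any(events$onset + events$duration > run_len))
    stop("events exceed the run length of ", run_len, " s")
  for (r in regions) stopifnot(grids_equal(grid, r$grid))
  S <- vapply(events$onset, .convolved_regressor, numeric(n_volumes),
              n_volumes = n_volumes, tr = tr)
  A <- .trial_amplitudes(events, regions, params)
  if (!is.null(mask)) A <- A[, mask$idx, drop = FALSE]
  nvox <- ncol(A)
  Y <- S %*% A
  nm <- params$noise
  if (nm$drift_amplitude > 0) {
    ph <- runif(1, 0, 2 * pi)
    scale_v <- runif(nvox, 0.5, 1.5) * nm$drift_amplitude
    tsec <- (seq_len(n_volumes) - 1) * tr
    Y <- Y + cos(2 * pi * tsec / nm$drift_period_s + ph) %o% scale_v
  }
  if (nm$white_sd > 0) {
    innov_sd <- nm$white_sd * sqrt(1 - nm$ar1_rho^2)
    E <- matrix(rnorm(n_volumes * nvox, 0, innov_sd), n_volumes, nvox)
    if (nm$ar1_rho != 0)
      for (t in 2:n_volumes) E[t, ] <- E[t, ] + nm$ar1_rho * E[t - 1L, ]
    Y <- Y + E
  }
  Y <- Y + baseline
  if (!is.null(mask)) {
    attr(Y, "mask") <- mask
    return(Y)
  }
  out <- array(t(Y), c(grid$shape, n_volumes))
  attr(out, "grid") <- grid
  out
}

#' Draw behavioural responses for the test phase
#'
#' Per-trial Bernoulli draws with group-specific hit and correct-rejection
#' probabilities; the subject's own rates are drawn around the group means
#' with SDs \code{p_hit_sd}/\code{p_cr_sd} (between-subject heterogeneity,
#' calibrated so simulated trial-count SDs match the reported group
#' tables); optionally a no-response probability. Study trials inherit the
#' subsequent-memory outcome of their adjective's test trial.
#'
#' @param events full \code{event_table} (study + test runs).
#' @param behavior list with \code{p_hit}, \code{p_cr}, \code{p_none} and
#'   optionally \code{p_hit_sd}, \code{p_cr_sd}.
#' @return the event table with \code{response} and \code{outcome} filled.
#' @export
simulate_behavior <- function(events, behavior) {
  te <- events$phase == "test"
  n <- sum(te)
  intact <- events$status[te] == "intact"
  clip01 <- function(p) pmin(0.999, pmax(0.001, p))
  p_hit <- clip01(behavior$p_hit + rnorm(1, 0, behavior$p_hit_sd %||% 0))
  p_cr <- clip01(behavior$p_cr + rnorm(1, 0, behavior$p_cr_sd %||% 0))
  resp <- character(n)
  resp[intact] <- ifelse(runif(sum(intact)) < p_hit, "old", "new")
  resp[!intact] <- ifelse(runif(sum(!intact)) < p_cr, "new", "old")
  if (behavior$p_none > 0)
    resp[runif(n) < behavior$p_none] <- "none"
  events$response[te] <- resp
  events$outcome[te] <- classify_outcome(events$status[te], resp)
  # subsequent-memory outcome for study trials
  m <- match(events$adjective[!te], events$adjective[te])
  events$outcome[!te] <- events$outcome[te][m]
  events$response[!te] <- NA_character_
  events
}

#' Simulate one subject in memory
#'
#' Design + behaviour + six runs (3 study, 3 test) for one subject.
#'
#' @param preset a \code{\link{cohort_presets}} list.
#' @param grid,regions geometry (see \code{\link{default_regions}}).
#' @param seed RNG seed for the subject.
#' @param tr,n_volumes,n_pairs,n_lists acquisition and design parameters.
#' @param counterbalance 1 or 2.
#' @param mask optional mask for the fast matrix path (see
#'   \code{\link{simulate_run}}).
#' @return list: \code{events} (all runs), \code{runs} (list of 4D
#'   arrays, or \code{time x voxel} matrices when \code{mask} is given,
#'   in run order), \code{params} (ground-truth subject state).
#' @export
simulate_subject <- function(preset, grid, regions, seed = NULL, tr = 2,
                             n_volumes = 205, n_pairs = 192L, n_lists = 3L,
                             counterbalance = 1L, mask = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pairs <- make_lists(n_pairs = n_pairs, n_lists = n_lists,
                      counterbalance = counterbalance)
  events <- build_event_tables(pairs)
  events <- simulate_behavior(events, preset$behavior)
  params <- subject_params(preset, regions)
  runs <- lapply(sort(unique(events$run)), function(r)
    simulate_run(events[events$run == r, ], grid, regions, params,
                 tr = tr, n_volumes = n_volumes, mask = mask))
  list(events = events, runs = runs, params = params)
}

#' Simulate a two-group cohort to disk
#'
#' Writes a BIDS-like tree: per subject \code{sub-XX/func/} with one
#' NIfTI-1 run (\code{_bold.nii}) and one events TSV per run, shared
#' region masks under \code{masks/}, and \code{ground_truth.json} with the
#' seeds, group assignments and planted parameters.
#'
#' @param out_dir output directory (created).
#' @param n_per_group subjects per group (default 20).
#' @param presets named list of two \code{\link{cohort_presets}} (default
#'   young and old).
#' @param grid a \code{\link{volume_grid}} (default the full 3 mm grid).
#' @param regions region list (default \code{\link{default_regions}}).
#' @param seed base RNG seed; subject s uses \code{seed + s}.
#' @param tr,n_volumes,n_pairs,n_lists acquisition/design parameters.
#' @return the dataset directory, invisibly.
#' @export
simulate_cohort <- function(out_dir, n_per_group = 20L,
                            presets = list(young = cohort_presets("young"),
                                           old = cohort_presets("old")),
                            grid = volume_grid(c(30, 36, 24)),
                            regions = default_regions(grid),
                            seed = 1L, tr = 2, n_volumes = 205,
                            n_pairs = 192L, n_lists = 3L) {
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  for (nm in names(regions))
    write_nifti(array(as.numeric(regions[[nm]]$mask), grid$shape),
                file.path(out_dir, "masks", paste0(nm, ".nii")), grid,
                datatype = "uint8")
  groups <- rep(names(presets), each = n_per_group)
  truth <- list(seed = seed, n_per_group = n_per_group, tr = tr,
                n_volumes = n_volumes, grid_shape = grid$shape,
                voxel_mm = grid$voxel_mm, subjects = list())
  for (s in seq_along(groups)) {
    sid <- sprintf("sub-%02d", s)
    subj_seed <- seed + s
    cb <- 1L + (s %% 2L)
    sim <- simulate_subject(presets[[groups[s]]], grid, regions,
                            seed = subj_seed, tr = tr,
                            n_volumes = n_volumes, n_pairs = n_pairs,
                            n_lists = n_lists, counterbalance = cb)
    fdir <- file.path(out_dir, sid, "func")
    dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
    for (r in seq_along(sim$runs)) {
      write_nifti(sim$runs[[r]],
                  file.path(fdir, sprintf("%s_run-%02d_bold.nii", sid, r)),
                  grid, tr = tr)
      write_events_tsv(sim$events[sim$events$run == r, ],
                       file.path(fdir, sprintf("%s_run-%02d_events.tsv",
                                               sid, r)))
    }
    truth$subjects[[sid]] <- list(
      group = groups[s], seed = subj_seed, counterbalance = cb,
      pattern_weights = unclass(sim$params$pattern),
      expected_similarity = as.list(expected_similarity(sim$params$pattern)))
  }
  truth$presets <- lapply(presets, function(p) list(
    group = p$group,
    pattern = unclass(p$pattern),
    behavior = p$behavior,
    kappa = p$connectivity$kappa,
    amplitudes = p$activation$amplitudes))
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
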