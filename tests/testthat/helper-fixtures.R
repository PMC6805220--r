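# Shared fixtures: a reduced 3 mm grid with non-overlapping toy regions and
# fast in-memory cohort simulation. The reduced grid keeps the full design
# (6 runs x 64 trials, 205 volumes, TR 2 s) but shrinks the spatial extent;
# only voxels inside the analysis mask are simulated on the fast path,
# which is statistically identical to full-grid simulation without
# smoothing because voxel noise is independent.

test_grid <- function() volume_grid(c(12, 12, 8), 3)

test_regions <- function(grid = test_grid())
  default_regions(grid, cortical_radius_mm = 5, hipp_radius_mm = 5)

test_brain_mask <- function(regions)
  roi_union(regions[setdiff(names(regions), "HIPP_PEAK")], name = "brain")

# simulate + analyse one subject on the fast masked path
quick_subject <- function(group = "young", seed = 1L, counterbalance = 1L,
                          preset = cohort_presets(group),
                          grid = test_grid(),
                          regions = test_regions(grid)) {
  mask <- test_brain_mask(regions)
  sim <- simulate_subject(preset, grid, regions, seed = seed,
                          counterbalance = counterbalance, mask = mask)
  res <- suppressWarnings(
    analyze_subject(sim$runs, sim$events, regions, grid,
                    options = analysis_options(smoothing_fwhm_mm = 0),
                    brain_mask = mask))
  res$sim <- sim
  res
}

# simulate + analyse a two-group cohort in memory; returns aggregate tables
quick_cohort <- function(n_per_group, rep_seed,
                         groups = c("young", "old"),
                         preset_names = groups,
                         grid = test_grid(),
                         regions = test_regions(grid)) {
  mask <- test_brain_mask(regions)
  presets <- setNames(lapply(preset_names, cohort_presets), groups)
  set.seed(rep_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_per_group)
  per <- list()
  for (i in seq_len(2L * n_per_group)) {
    grp <- groups[1L + (i > n_per_group)]
    sim <- simulate_subject(presets[[grp]], grid, regions, seed = seeds[i],
                            counterbalance = 1L + (i %% 2L), mask = mask)
    r <- suppressWarnings(
      analyze_subject(sim$runs, sim$events, regions, grid,
                      options = analysis_options(smoothing_fwhm_mm = 0),
                      brain_mask = mask))
    r$group <- grp
    per[[sprintf("s%03d", i)]] <- r
  }
  suppressMessages(aggregate_results(per))
}

# minimal single-run event table for GLM tests
toy_events <- function(onsets, outcome = "hit", run = 1L, phase = "test",
                       picture = "umbrella", status = "intact") {
  n <- length(onsets)
  ev <- data.frame(run = run, phase = phase, block = 1L, trial = seq_len(n),
                   onset = onsets, duration = 5,
                   adjective = sprintf("adj_%04d", seq_len(n)),
                   picture = rep_len(picture, n),
                   studied_picture = rep_len(picture, n),
                   subcategory = "inanimate", category = "object",
                   status = rep_len(status, n), response = NA_character_,
                   outcome = rep_len(outcome, n), stringsAsFactors = FALSE)
  class(ev) <- c("event_table", "data.frame")
  ev
}
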