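# Representational similarity: matrices, Fisher z, level means, group stats.

# build a beta_stack directly from a trial x voxel matrix
stack_of <- function(B, trials, grid = volume_grid(c(5, 2, 1), 3)) {
  mask <- roi_mask(seq_len(ncol(B)), grid, name = "m")
  structure(list(betas = B, trials = trials, mask = mask),
            class = "beta_stack")
}

test_that("similarity matrix matches hand-computed Pearson values", {
  trials <- data.frame(run = c(1, 2, 2), picture = "umbrella",
                       stringsAsFactors = FALSE)
  B <- rbind(c(1, 2, 3), c(1, 2, 4), c(-1, -2, -3))
  S <- similarity_matrix(stack_of(B, trials),
                         roi_mask(1:3, volume_grid(c(5, 2, 1), 3)))
  expect_equal(diag(S), rep(1, 3))
  expect_equal(S[1, 2], 0.982, tolerance = 1e-3)   # hand Pearson
  expect_equal(S[1, 3], -1)                        # exact negation
  expect_equal(S, t(S))
})

test_that("zero-variance patterns yield NA entries with a warning", {
  trials <- data.frame(run = c(1, 2), picture = "umbrella",
                       stringsAsFactors = FALSE)
  B <- rbind(c(1, 1, 1), c(1, 2, 3))
  expect_warning(S <- similarity_matrix(stack_of(B, trials),
                                        roi_mask(1:3, volume_grid(c(5, 2, 1), 3))),
                 "zero-variance")
  expect_true(is.na(S[1, 2]))
  expect_equal(S[2, 2], 1)
})

test_that("fisher_z is arctanh with clipping at |r| = 1", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(fisher_z(-r), -fisher_z(r))       # odd symmetry
  expect_equal(fisher_z(0.3), atanh(0.3))
  expect_warning(z <- fisher_z(1), "clipped")
  expect_true(is.finite(z))
})

# a balanced two-run toy: 16 trials, 8 pictures x 2 runs
toy_rsa_trials <- function() {
  h <- stimulus_hierarchy()
  data.frame(run = rep(1:2, each = 8), picture = rep(h$exemplar, 2),
             outcome = "hit", stringsAsFactors = FALSE)
}

test_that("level means use across-run pairs only and report difference scores", {
  set.seed(3)
  trials <- toy_rsa_trials()
  B <- matrix(rnorm(16 * 30), 16)
  S <- similarity_matrix(stack_of(B, trials,
                                  grid = volume_grid(c(30, 1, 1), 3)),
                         roi_mask(1:30, volume_grid(c(30, 1, 1), 3)))
  lm1 <- level_means(S)
  expect_named(lm1$level_z, c("SE", "SS", "SC", "DC"))
  expect_equal(unname(lm1$scores),
               unname(c(lm1$level_z["SE"] - lm1$level_z["SS"],
                        lm1$level_z["SS"] - lm1$level_z["SC"],
                        lm1$level_z["SC"] - lm1$level_z["DC"])))
  # across-run pair counts for this balanced design: 8 SE, 8 SS, 16 SC, 32 DC
  expect_equal(lm1$n_pairs, c(8L, 8L, 16L, 32L))
  # perturbing within-run entries must not change anything
  S2 <- S
  within <- outer(trials$run, trials$run, "==")
  S2[within & upper.tri(S2)] <- 0.99
  S2[within & lower.tri(S2)] <- 0.99
  attr(S2, "trials") <- trials
  lm2 <- level_means(S2)
  expect_equal(lm2$level_z, lm1$level_z)
  # trial order must not matter
  ord <- sample(16)
  S3 <- S[ord, ord]
  attr(S3, "trials") <- trials[ord, ]
  expect_equal(level_means(S3)$level_z, lm1$level_z)
})

test_that("identical patterns give equal level means at the clip bound", {
  trials <- toy_rsa_trials()
  B <- matrix(rep(rnorm(30), each = 16), 16)
  suppressWarnings({
    S <- similarity_matrix(stack_of(B, trials,
                                    grid = volume_grid(c(30, 1, 1), 3)),
                           roi_mask(1:30, volume_grid(c(30, 1, 1), 3)))
    lm1 <- level_means(S)
  })
  expect_equal(length(unique(round(lm1$level_z, 6))), 1L)
})

test_that("single-run data cannot form across-run pairs", {
  trials <- toy_rsa_trials()
  trials$run <- 1L
  B <- matrix(rnorm(16 * 10), 16)
  suppressWarnings(
    S <- similarity_matrix(stack_of(B, trials,
                                    grid = volume_grid(c(10, 1, 1), 3)),
                           roi_mask(1:10, volume_grid(c(10, 1, 1), 3))))
  expect_error(level_means(S), "no across-run pairs")
})

test_that("correct_only filter drops incorrect trials from the pair set", {
  set.seed(9)
  trials <- toy_rsa_trials()
  trials$outcome[trials$picture == "umbrella"] <- "miss"
  B <- matrix(rnorm(16 * 30), 16)
  S <- similarity_matrix(stack_of(B, trials,
                                  grid = volume_grid(c(30, 1, 1), 3)),
                         roi_mask(1:30, volume_grid(c(30, 1, 1), 3)))
  lm_all <- level_means(S)
  lm_cor <- level_means(S, accuracy_filter = "correct_only")
  expect_lt(lm_cor$n_pairs[1], lm_all$n_pairs[1])
  # umbrella trials cannot contribute: altering their rows changes nothing
  S2 <- S
  um <- which(trials$picture == "umbrella")
  S2[um, ] <- 0.5; S2[, um] <- 0.5; diag(S2) <- 1
  attr(S2, "trials") <- trials
  expect_equal(level_means(S2, accuracy_filter = "correct_only")$level_z,
               lm_cor$level_z)
})

test_that("group stats: identical groups give a null interaction, zero scores give t = 0", {
  lev <- relatedness_levels()
  set.seed(44)
  base <- expand.grid(subject = sprintf("s%02d", 1:8), level = lev,
                      stringsAsFactors = FALSE)
  base$value <- rep(c(0.4, 0.3, 0.2, 0.1), each = 8) + rnorm(32, 0, 0.05)
  two <- rbind(cbind(base, group = "young", stringsAsFactors = FALSE),
               transform(base, subject = sub("s", "t", subject),
                         group = "old"))
  st <- group_rsa_stats(two)
  expect_lt(st$anova$F[st$anova$effect == "group:level"], 1e-10)
  # subject-only variation: every difference score is exactly zero (t = 0)
  # while levels still vary between subjects
  flat <- two
  offs <- rnorm(16, 0, 0.1)
  flat$value <- offs[match(flat$subject, unique(flat$subject))]
  st2 <- group_rsa_stats(flat)
  expect_true(all(st2$score_tests$t == 0))
  expect_lt(st2$anova$F[st2$anova$effect == "level"], 1e-10)
})

test_that("similarity matrices roundtrip through CSV with trial headers", {
  set.seed(21)
  trials <- toy_rsa_trials()
  trials$trial <- seq_len(16)
  B <- matrix(rnorm(16 * 30), 16)
  S <- similarity_matrix(stack_of(B, trials,
                                  grid = volume_grid(c(30, 1, 1), 3)),
                         roi_mask(1:30, volume_grid(c(30, 1, 1), 3)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_similarity_csv(S, path)
  back <- read_similarity_csv(path)
  expect_equal(unname(back), unname(S), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(attr(back, "trials")$picture, trials$picture)
  expect_equal(level_means(back)$level_z, level_means(S)$level_z,
               tolerance = 1e-10)
})

test_that("young-preset cohort recovers the planted level ordering", {
  agg <- quick_cohort(4, rep_seed = 881)
  ym <- with(subset(agg$rsa_levels, group == "young"),
             tapply(value, level, mean))[relatedness_levels()]
  expect_true(all(diff(ym) < 0))  # SE > SS > SC > DC
  # estimation noise attenuates the whole profile by a common factor:
  # the measured profile should match the closed-form oracle after
  # fitting that single factor
  z <- fisher_z(expected_similarity(cohort_presets("young")$pattern))
  lambda <- sum(ym * z) / sum(z * z)
  expect_gt(lambda, 0.2)
  expect_lt(max(abs(ym - lambda * z)), 0.06)
})
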