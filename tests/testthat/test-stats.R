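# Behavioural scoring and inferential statistics.

make_test_events <- function(n_intact = 96, n_recombined = 96,
                             resp_intact = "old", resp_recombined = "new") {
  n <- n_intact + n_recombined
  data.frame(phase = "test",
             status = c(rep("intact", n_intact), rep("recombined", n_recombined)),
             response = c(rep_len(resp_intact, n_intact),
                          rep_len(resp_recombined, n_recombined)),
             stringsAsFactors = FALSE)
}

test_that("score_behavior classifies outcomes and computes corrected recognition", {
  perfect <- score_behavior(make_test_events())
  expect_equal(perfect$hits, 96L)
  expect_equal(perfect$crs, 96L)
  expect_equal(perfect$corrected_recognition, 1)
  # trial-count identities
  mixed <- make_test_events(resp_intact = c("old", "new", "none"),
                            resp_recombined = c("new", "old"))
  s <- score_behavior(mixed)
  expect_equal(s$hits + s$misses + sum(mixed$status == "intact" &
                                         mixed$response == "none"), 96L)
  expect_equal(s$crs + s$fas + sum(mixed$status == "recombined" &
                                     mixed$response == "none"), 96L)
  expect_error(score_behavior(make_test_events(resp_intact = "maybe")),
               "unknown response")
})

test_that("a subject at the printed group means scores corrected recognition 0.826", {
  # 85.05 hits and 5.75 FAs out of 96 each
  ev <- make_test_events(resp_intact = c(rep("old", 85), rep("new", 11)),
                         resp_recombined = c(rep("old", 6), rep("new", 90)))
  s <- score_behavior(ev)
  expect_equal(s$corrected_recognition, 85 / 96 - 6 / 96)
  expect_equal(85.05 / 96 - 5.75 / 96, 0.826, tolerance = 1e-3)
})

test_that("random responding yields corrected recognition near zero", {
  set.seed(8)
  cr <- replicate(200, {
    ev <- make_test_events(
      resp_intact = sample(c("old", "new"), 96, replace = TRUE),
      resp_recombined = sample(c("old", "new"), 96, replace = TRUE))
    score_behavior(ev)$corrected_recognition
  })
  expect_lt(abs(mean(cr)), 3 * sd(cr) / sqrt(length(cr)))
})

test_that("denominator switch excludes no-responses", {
  ev <- make_test_events(resp_intact = c(rep("old", 90), rep("none", 6)),
                         resp_recombined = "new")
  presented <- score_behavior(ev)
  responded <- score_behavior(ev, denominator = "responded")
  expect_equal(presented$p_hit, 90 / 96)
  expect_equal(responded$p_hit, 1)
})

test_that("pooled t reproduces the printed group comparison", {
  tt <- independent_t(85.05, 7.3, 20, 71.90, 10.3, 20)
  expect_equal(tt$t, 4.67, tolerance = 0.005)
  expect_equal(tt$df, 38)
  expect_lt(tt$p, 0.001)
  # vector interface agrees with stats::t.test
  set.seed(10)
  x <- rnorm(15, 1); y <- rnorm(12)
  mine <- independent_t(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(mine$t, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value)
  welch <- independent_t(x, y, var_equal = FALSE)
  ref_w <- t.test(x, y)
  expect_equal(welch$t, unname(ref_w$statistic))
  expect_equal(welch$df, unname(ref_w$parameter))
  expect_equal(independent_t(1, 1, 5, 1, 1, 5)$t, 0)
  expect_error(independent_t(1, 0, 5, 1, 0, 5), "zero variance")
})

test_that("paired t matches stats::t.test and is antisymmetric", {
  set.seed(11)
  a <- rnorm(10); b <- rnorm(10)
  mine <- paired_t(a, b)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(mine$t, unname(ref$statistic))
  expect_equal(mine$df, unname(ref$parameter))
  expect_equal(mine$p, ref$p.value)
  expect_equal(paired_t(b, a)$t, -mine$t)
  expect_equal(paired_t(a, a)$t, 0)
})

test_that("mixed ANOVA matches the aov oracle on a balanced 2 x 4 design", {
  set.seed(12)
  d <- expand.grid(subject = sprintf("s%02d", 1:10),
                   level = c("SE", "SS", "SC", "DC"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(d$subject %in% sprintf("s%02d", 1:5), "young", "old")
  d$value <- rnorm(nrow(d)) + as.numeric(factor(d$level)) * 0.3 +
    (d$group == "old") * 0.5
  mine <- mixed_anova(d)
  oracle <- summary(aov(value ~ group * level + Error(subject / level),
                        data = transform(d, subject = factor(subject),
                                         group = factor(group),
                                         level = factor(level))))
  f_between <- oracle[["Error: subject"]][[1]]
  f_within <- oracle[["Error: subject:level"]][[1]]
  expect_equal(mine$F[mine$effect == "group"], f_between["group", "F value"],
               tolerance = 1e-8)
  expect_equal(mine$F[mine$effect == "level"], f_within["level", "F value"],
               tolerance = 1e-8)
  expect_equal(mine$F[mine$effect == "group:level"],
               f_within["group:level", "F value"], tolerance = 1e-8)
  expect_equal(mine$p[mine$effect == "group:level"],
               f_within["group:level", "Pr(>F)"], tolerance = 1e-8)
})

test_that("two-level within effect equals the squared paired t", {
  set.seed(13)
  n <- 14
  subj <- sprintf("s%02d", 1:n)
  hit <- rnorm(n, 1); cr <- rnorm(n, 0.6)
  # the exact identity holds in the one-group reduction, where the
  # within-error stratum is the full between-subject variance of the
  # condition difference
  d <- rbind(data.frame(subject = subj, group = "all", level = "hit",
                        value = hit, stringsAsFactors = FALSE),
             data.frame(subject = subj, group = "all", level = "CR",
                        value = cr, stringsAsFactors = FALSE))
  an <- mixed_anova(d)
  tt <- paired_t(hit, cr)
  expect_equal(an$F[an$effect == "level"], tt$t^2, tolerance = 1e-8)
  expect_equal(an$p[an$effect == "level"], tt$p, tolerance = 1e-8)
})

test_that("degenerate inputs are rejected, all-equal data give F = 0", {
  flat <- expand.grid(subject = sprintf("s%d", 1:6), level = c("a", "b"),
                      stringsAsFactors = FALSE)
  flat$group <- rep(c("g1", "g2"), 6)[match(flat$subject,
                                            unique(flat$subject))]
  flat$group <- ifelse(flat$subject %in% sprintf("s%d", 1:3), "g1", "g2")
  flat$value <- 1
  an <- mixed_anova(flat)
  expect_true(all(an$F[!is.na(an$F)] == 0))
  expect_error(mixed_anova(flat[-1, ]), "missing cells")
})

test_that("mixed ANOVA interaction is calibrated under a pure group shift", {
  set.seed(14)
  n_rep <- 500
  stats <- replicate(n_rep, {
    d <- expand.grid(subject = sprintf("s%02d", 1:8),
                     level = c("l1", "l2"), stringsAsFactors = FALSE)
    d$group <- ifelse(d$subject %in% sprintf("s%02d", 1:4), "a", "b")
    d$value <- rnorm(nrow(d)) + (d$group == "a") * 2  # group shift only
    an <- mixed_anova(d)
    c(F = an$F[an$effect == "group:level"],
      p = an$p[an$effect == "group:level"])
  })
  # null interaction: mean F equals its null expectation df2/(df2 - 2)
  # (here (8 - 2) * (2 - 1) = 6 error df, so E[F] = 1.5)
  expect_equal(mean(stats["F", ]), 6 / 4, tolerance = 0.25)
  rate <- mean(stats["p", ] < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep) + 1e-9)
})

test_that("independent and paired t tests hold their nominal size", {
  set.seed(15)
  n_rep <- 1000
  p_ind <- replicate(n_rep, independent_t(rnorm(8), rnorm(8))$p)
  p_par <- replicate(n_rep, paired_t(rnorm(8), rnorm(8))$p)
  se3 <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(p_ind < 0.05) - 0.05), se3)
  expect_lt(abs(mean(p_par < 0.05) - 0.05), se3)
})

test_that("bonferroni thresholds match the printed values", {
  expect_equal(bonferroni_threshold(0.05, 4), 0.0125)
  expect_equal(round(bonferroni_threshold(0.05, 3), 4), 0.0167)
  expect_equal(bonferroni_threshold(0.07, 1), 0.07)
  expect_error(bonferroni_threshold(0.05, 0))
})
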