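# GLM layer: HRF, drift basis, designs, fitting, scaling, smoothing.

test_that("canonical HRF peaks near 5 s and has the double-gamma shape", {
  h <- canonical_hrf(0.1)
  # independent oracle: maximise the double-gamma difference numerically
  g <- function(t) dgamma(t, 6, 1) - dgamma(t, 16, 1) / 6
  t_peak <- stats::optimize(g, c(0, 32), maximum = TRUE)$maximum
  expect_equal((which.max(h) - 1) * 0.1, round(t_peak, 1), tolerance = 1e-9)
  expect_gt(sum(h), 0)
  expect_lt(min(h), 0)                       # undershoot
  expect_equal(max(h), 1, tolerance = 1e-6)  # peak-normalised
})

test_that("coarse HRF sampling is an exact subsample of fine sampling", {
  h_fine <- canonical_hrf(0.1)
  h_tr <- canonical_hrf(2.0)
  expect_equal(h_tr, h_fine[seq(1, length(h_fine), by = 20)])
})

test_that("high-pass basis follows the K = floor(2nT/cutoff) convention", {
  expect_equal(ncol(highpass_basis(205, 2, 128)), 6L)
  expect_equal(ncol(highpass_basis(205, 2, Inf)), 0L)
  X <- highpass_basis(205, 2)
  expect_equal(unname(colSums(X)), rep(0, 6), tolerance = 1e-10)  # orthogonal to 1
  # a drift at an exact basis frequency is removed by projection
  t <- 0:204
  drift <- cos(pi * (2 * t + 1) * 3 / (2 * 205))
  P <- cbind(X, 1)
  resid <- drift - P %*% qr.coef(qr(P), drift)
  expect_lt(max(abs(resid)), 1e-10)
  # a generic 200 s-period drift (beyond the 128 s cutoff) is attenuated
  slow <- cos(2 * pi * t * 2 / 200)
  resid2 <- slow - P %*% qr.coef(qr(P), slow)
  expect_lt(sqrt(mean(resid2^2)) / sqrt(mean(slow^2)), 0.15)
})

test_that("condition design: single-event identity and superposition", {
  ev1 <- toy_events(0)
  D <- build_condition_design(ev1, 20, 2, conditions = list(hit = "hit"))
  h <- canonical_hrf(0.1)
  expect_equal(D$X[, "hit"][1:17], h[seq(1, length(h), by = 20)],
               tolerance = 1e-12)
  # superposition: two overlapping events = sum of shifted single events
  ev2 <- toy_events(c(10, 16))
  D2 <- build_condition_design(ev2, 40, 2, conditions = list(hit = "hit"))
  Da <- build_condition_design(toy_events(10), 40, 2,
                               conditions = list(hit = "hit"))
  Db <- build_condition_design(toy_events(16), 40, 2,
                               conditions = list(hit = "hit"))
  expect_equal(D2$X[, "hit"], Da$X[, "hit"] + Db$X[, "hit"],
               tolerance = 1e-12)
})

test_that("empty conditions are dropped with a record", {
  ev <- toy_events(c(10, 40), outcome = "hit")
  ws <- capture_warnings(D <- build_condition_design(ev, 60, 2))
  expect_true(all(grepl("no trials", ws)))
  expect_length(ws, 2L)
  expect_true(all(c("cr", "other") %in% D$dropped))
  expect_false("cr" %in% D$names)
})

test_that("fit_glm recovers planted amplitudes exactly on noiseless data", {
  ev <- toy_events(c(12, 30, 60, 90))
  D <- build_condition_design(ev, 80, 2, conditions = list(hit = "hit"))
  planted <- c(2.5, 0.4, -0.2, 7)  # hit, dct1, dct2, intercept
  Y <- cbind(D$X %*% planted[seq_len(ncol(D$X))],
             D$X %*% rev(planted[seq_len(ncol(D$X))]))
  fit <- fit_glm(Y, D)
  expect_equal(unname(fit$beta[, 1]), planted[seq_len(ncol(D$X))],
               tolerance = 1e-10)
  expect_equal(fit$df, 80 - ncol(D$X))
})

test_that("OLS matches the brute-force normal equations on a toy", {
  set.seed(7)
  ev <- toy_events(c(4, 22, 50))
  D <- build_condition_design(ev, 50, 2, conditions = list(hit = "hit"))
  Y <- matrix(rnorm(50 * 10), 50, 10)
  fit <- fit_glm(Y, D)
  oracle <- solve(t(D$X) %*% D$X) %*% t(D$X) %*% Y
  expect_equal(unname(fit$beta), unname(oracle), tolerance = 1e-8)
})

test_that("rank-deficient designs fail with the collinear columns named", {
  X <- cbind(a = rep(1, 10), b = rep(2, 10))
  D <- structure(list(X = X, names = colnames(X), interest = 1:2,
                      n_volumes = 10, tr = 2), class = "design_matrix")
  expect_error(fit_glm(matrix(rnorm(10), 10, 1), D), "collinear")
})

test_that("AR(1) prewhitening recovers rho and reduces to OLS when rho = 0", {
  set.seed(21)
  n <- 400; rho <- 0.3
  ev <- toy_events(seq(10, 760, by = 30))
  D <- build_condition_design(ev, n, 2, conditions = list(hit = "hit"))
  e <- matrix(rnorm(n * 30), n, 30)
  for (t in 2:n) e[t, ] <- rho * e[t - 1, ] + e[t, ]
  Y <- matrix(D$X %*% c(1.5, numeric(ncol(D$X) - 1)), n, 30) + e
  fit <- fit_glm(Y, D, whitening = "ar1")
  expect_lt(abs(fit$rho - rho), 0.05)
  # white noise: whitened fit is numerically close to OLS
  Yw <- matrix(D$X %*% c(1.5, numeric(ncol(D$X) - 1)), n, 30) +
    matrix(rnorm(n * 30), n, 30)
  f0 <- fit_glm(Yw, D)
  f1 <- fit_glm(Yw, D, whitening = "ar1")
  expect_lt(abs(f1$rho), 0.05)
  expect_equal(unname(f1$beta[1, ]), unname(f0$beta[1, ]), tolerance = 0.02)
})

test_that("drift columns leave interest betas unchanged on drift-free data", {
  ev <- toy_events(c(12, 48, 96))
  D_full <- build_condition_design(ev, 100, 2,
                                   conditions = list(hit = "hit"))
  D_bare <- build_condition_design(ev, 100, 2,
                                   conditions = list(hit = "hit"),
                                   cutoff_s = Inf)
  Y <- D_bare$X %*% c(3, 5)  # signal + intercept only, no drift
  b_full <- fit_glm(Y, D_full)$beta["hit", 1]
  b_bare <- fit_glm(Y, D_bare)$beta["hit", 1]
  expect_equal(b_full, b_bare, tolerance = 1e-8)
})

test_that("single-trial design has one regressor per trial across runs", {
  pairs <- make_lists(seed = 31)
  ev <- build_event_tables(pairs, seed = 31)
  ev$outcome <- "hit"
  study <- split(ev[ev$phase == "study", ],
                 ev$run[ev$phase == "study"])
  D <- single_trial_design(study, 205, 2)
  expect_length(D$interest, 192L)
  expect_equal(nrow(D$X), 3 * 205)
  expect_equal(nrow(D$trials), 192L)
  # session nuisance: 6 drifts + mean per run
  expect_equal(ncol(D$X), 192L + 3L * 7L)
  expect_error(single_trial_design(list(study[[1]], study[[1]]), 205, 2),
               "duplicate")
})

test_that("single-trial betas equal planted per-trial amplitudes when noiseless", {
  ev <- toy_events(c(12, 18, 24, 48), run = 1L)
  D <- single_trial_design(list(ev), 60, 2)
  planted <- c(1, -0.5, 2, 0.25)
  Y <- D$X %*% c(planted, numeric(ncol(D$X) - 4))
  fit <- fit_glm(Y, D)
  expect_equal(unname(fit$beta[1:4, 1]), planted, tolerance = 1e-10)
})

test_that("percent signal change is linear and recovers a planted 1%", {
  ev <- toy_events(seq(12, 350, by = 24))
  D <- build_condition_design(ev, 200, 2, conditions = list(hit = "hit"))
  amp <- 1  # 1% of baseline 100
  Y <- 100 + D$X[, "hit", drop = FALSE] %*% amp
  fit <- fit_glm(Y, D)
  p1 <- unname(percent_signal_change(fit, "hit"))
  expect_equal(p1, 1, tolerance = 0.05)
  # linearity: doubling the coefficient doubles the scaled value exactly
  fit2 <- fit; fit2$beta <- 2 * fit$beta
  expect_equal(unname(percent_signal_change(fit2, "hit")), 2 * p1,
               tolerance = 1e-12)
  # constant run: zero beta, zero PSC
  fit0 <- fit_glm(matrix(100, 200, 1), D)
  expect_equal(unname(percent_signal_change(fit0, "hit")), 0,
               tolerance = 1e-10)
})

test_that("contrast_map is the weighted beta sum", {
  ev <- toy_events(c(12, 40), outcome = c("hit", "CR"))
  D <- build_condition_design(ev, 60, 2,
                              conditions = list(hit = "hit", cr = "CR"))
  Y <- D$X %*% c(2, 5, numeric(ncol(D$X) - 2))
  fit <- fit_glm(Y, D)
  expect_equal(unname(contrast_map(fit, c(1, 0))), 2, tolerance = 1e-8)
  expect_equal(unname(contrast_map(fit, c(1, -1))), -3, tolerance = 1e-8)
  expect_equal(unname(contrast_map(fit, c(1, -1))),
               unname(fit$beta[1, ] - fit$beta[2, ]), tolerance = 1e-12)
})

test_that("Gaussian smoothing preserves constants and shrinks variance", {
  set.seed(5)
  x <- array(rnorm(10 * 10 * 6 * 2), c(10, 10, 6, 2))
  s <- smooth_volumes(x, 6, 3)
  expect_equal(dim(s), dim(x))
  expect_lt(var(as.numeric(s)), var(as.numeric(x)))
  const <- array(3.7, c(10, 10, 6))
  expect_equal(smooth_volumes(const, 8, 3), const, tolerance = 1e-10)
})
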