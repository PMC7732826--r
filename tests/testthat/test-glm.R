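TR <- 2.65

test_that("canonical HRF kernel has the documented shape", {
  k <- canonical_hrf(hrf_spec(), dt = 0.1)
  expect_equal(k[1], 0)                       # zero at t = 0
  expect_equal(max(k), 1, tolerance = 1e-6)   # unit peak
  expect_lt(min(k), 0)                        # undershoot
  # argmax within 0.2 s of the peak located on a dense grid of the
  # closed-form difference of gammas
  t_dense <- seq(0, 32, by = 1e-3)
  spec <- hrf_spec()
  raw <- dgamma(t_dense, spec$response_delay, 1) -
    dgamma(t_dense, spec$undershoot_delay, 1) / spec$ratio
  expect_lt(abs(0.1 * (which.max(k) - 1) - t_dense[which.max(raw)]), 0.2)
  # finite support
  expect_length(k, 320)
})

test_that("design structure and stick superposition", {
  acq <- acquisition_spec(TR = TR, n_scans = 60)
  blocks <- data.frame(onset = 10, duration = 80)
  ev0 <- data.frame(onset = numeric(0), duration = numeric(0),
                    regressor = character(0))
  d <- build_design(ev0, blocks, acq)
  expect_equal(colnames(d$X)[1:2], c("block", "go"))
  expect_equal(tail(colnames(d$X), 1), "intercept")
  expect_true(all(grepl("^dct", setdiff(colnames(d$X),
                                        c("block", "go", "intercept")))))

  # two sticks 30 s apart equal the sum of the two single-stick columns
  e2 <- data.frame(onset = c(40, 70), duration = 0, regressor = "ev")
  e_a <- data.frame(onset = 40, duration = 0, regressor = "ev")
  e_b <- data.frame(onset = 70, duration = 0, regressor = "ev")
  d2 <- build_design(e2, blocks, acq)
  da <- build_design(e_a, blocks, acq)
  db <- build_design(e_b, blocks, acq)
  expect_lt(max(abs(d2$X[, "ev"] - (da$X[, "ev"] + db$X[, "ev"]))), 1e-10)

  # zero-duration boxcar degenerates to the stick column
  e_d0 <- data.frame(onset = 40, duration = 0, regressor = "ev")
  expect_equal(build_design(e_d0, blocks, acq)$X[, "ev"], da$X[, "ev"])

  # events beyond the last scan are rejected, and listed
  e_late <- data.frame(onset = 1e4, duration = 0, regressor = "ev")
  expect_error(build_design(e_late, blocks, acq), "outside the scanned")

  # high-pass column count follows the cutoff
  expect_equal(ncol(dct_basis(60, TR, 128)) + 1,
               floor(2 * 60 * TR / 128 + 1))
})

test_that("model suite counts: one model per errorless ordinal plus five roles", {
  fx <- make_fixture("study-layout")
  s5 <- fx$seq
  tr <- parse_session(fx$keypresses, s5)
  sel <- select_errors(tr, selection_config())
  ctl <- enumerate_controls(tr)
  m <- match_positions(sel$periods, ctl, seed = 3)
  sj <- fx$keypresses$subject[1]
  models <- generate_model_suite(tr[tr$subject == sj, ], m, s5, fx$layout)
  expect_equal(sum(vapply(models, `[[`, "", "kind") == "ordinal"), 12L)
  expect_equal(sum(vapply(models, `[[`, "", "kind") == "role"), 5L)
  expect_equal(vapply(models[13:17], `[[`, "", "role"),
               c("PreE2", "PreE1", "E", "PostE1", "PostE2"))

  # a 6-trial-per-block layout gives 6 + 5 models
  lay6 <- block_layout(2L, 30L)
  spec6 <- behavior_gen_spec(n_subjects = 1L, layout = lay6, error_rate = 0,
                             seed = 5L)
  sim6 <- gen_behavior(spec6)
  tr6 <- parse_session(sim6$keypresses, s5)
  m0 <- match_positions(select_errors(tr6)$periods,
                        enumerate_controls(tr6), seed = 1)
  models6 <- generate_model_suite(tr6, m0, s5, lay6)
  expect_length(models6, 6L + 5L)

  # onset-policy equivalence: when every error's first key is its first
  # wrong key, trial_onset and first_wrong_key give identical events
  sched <- data.frame(subject = "sub01", block = 1L, trial = 6L,
                      type = "wrong_key", ordinal = 1L)
  spec1 <- behavior_gen_spec(n_subjects = 1L, layout = block_layout(1L, 60L),
                             error_schedule = sched, seed = 11L)
  sim1 <- gen_behavior(spec1)
  tr1 <- parse_session(sim1$keypresses, s5)
  m1 <- match_positions(select_errors(tr1)$periods,
                        enumerate_controls(tr1), seed = 1)
  mo_a <- generate_model_suite(tr1, m1, s5, spec1$layout,
                               onset_policy = "trial_onset")
  mo_b <- generate_model_suite(tr1, m1, s5, spec1$layout,
                               onset_policy = "first_wrong_key")
  ev_a <- apply_onset_policy(mo_a[[15]], sim1$keypresses)
  ev_b <- apply_onset_policy(mo_b[[15]], sim1$keypresses)
  expect_equal(ev_a$onset, ev_b$onset)
})

test_that("noiseless beta recovery and exact linear algebra", {
  # pure linear algebra: Y = X beta exactly recovered
  set.seed(2)
  X <- cbind(rnorm(50), rnorm(50), 1)
  colnames(X) <- c("a", "b", "intercept")
  beta <- c(2, -1, 0.5)
  fit <- fit_prewhitened(X %*% beta, X)
  expect_lt(max(abs(fit$beta[, 1] - beta)), 1e-8)

  # full generator-to-fitter recovery on grid-aligned onsets
  blocks <- data.frame(onset = c(6, 34) * TR, duration = c(18, 18) * TR)
  events <- data.frame(onset = c(8, 12, 36, 40) * TR, duration = 0,
                       regressor = rep(c("error", "control"), 2))
  spec <- bold_gen_spec(n_scans = 70,
                        betas = c(block = 1, go = 0.5, error = 2,
                                  control = 1),
                        sd = 0, drift_amplitude = 0)
  sim <- gen_bold(events, blocks, spec)
  des <- build_design(events, blocks, sim$acq)
  fit <- fit_prewhitened(sim$Y, des)
  for (rg in c("error", "control", "block", "go"))
    expect_lt(abs(fit$beta[rg, 1] / sim$truth$betas[rg, 1] - 1), 0.01)

  # rank-deficient designs are rejected naming the collinear column
  Xbad <- cbind(X, dup = X[, "a"])
  expect_error(fit_prewhitened(rnorm(50), Xbad), "collinear.*dup")
})

test_that("AR(1) prewhitening: phi recovery, beta bias, residual whitening", {
  n <- 400
  acq <- acquisition_spec(TR = TR, n_scans = n)
  blocks <- data.frame(onset = (0:6) * 150 + 20, duration = 60)
  events <- data.frame(onset = as.vector(outer((1:4) * 12, blocks$onset, "+")),
                       duration = 0, regressor = "ev")
  events <- events[events$onset < (n - 1) * TR - 40, , drop = FALSE]
  des <- build_design(events, blocks, acq)
  spec <- bold_gen_spec(n_scans = n, betas = c(block = 1, go = 0, ev = 1.5),
                        phi = 0.3, sd = 1, drift_amplitude = 0)
  sim0 <- gen_bold(events, blocks,
                   bold_gen_spec(n_scans = n,
                                 betas = c(block = 1, go = 0, ev = 1.5),
                                 sd = 0, drift_amplitude = 0))
  reps <- 200
  # one multi-series fit: 200 AR(1) noise realizations share the design
  set.seed(77)
  E <- vapply(seq_len(reps), function(r) {
    z <- rnorm(n + 50)
    e <- as.numeric(stats::filter(z, 0.3, method = "recursive"))
    e[-(1:50)] * sqrt(1 - 0.3^2)
  }, numeric(n))
  Y <- sim0$Y[, 1] + E
  fit <- fit_prewhitened(Y, des)
  # pooled phi close to the truth
  expect_lt(abs(fit$phi - 0.3), 0.05)
  # beta bias under 2 percent of the true value
  expect_lt(abs(mean(fit$beta["ev", ]) / 1.5 - 1), 0.02)
  expect_lt(abs(mean(fit$beta["block", ]) / 1 - 1), 0.02)
  # whitening pushes residual lag-1 autocorrelation toward zero
  r1 <- mean(vapply(seq_len(reps), function(j) {
    r <- fit$residuals[, j]
    sum(r[-1] * r[-n]) / sum(r^2)
  }, 0))
  expect_lt(abs(r1), 0.1)
  # white-noise input: estimated phi near zero
  set.seed(78)
  fitw <- fit_prewhitened(matrix(rnorm(n * 100), n), des)
  expect_lt(abs(fitw$phi), 0.05)
})

test_that("contrast arithmetic: selection, sign flip, null calibration", {
  set.seed(5)
  n <- 120
  X <- cbind(ev = as.numeric(arima.sim(list(ar = 0.5), n)), intercept = 1)
  beta <- c(1, 0)
  fit <- fit_prewhitened(X %*% beta, X)
  ct <- t_contrast(fit, c(ev = 1))
  expect_equal(ct$value, 1, tolerance = 1e-8)
  ctn <- t_contrast(fit, c(ev = -1))
  expect_equal(ctn$value, -ct$value)
  expect_error(t_contrast(fit, c(0, 0)), "all zero")
  expect_error(t_contrast(fit, c(bogus = 1)), "unknown regressor")

  # null calibration: 10,000 white-noise series against a real regressor
  set.seed(6)
  Y <- matrix(rnorm(n * 10000), n)
  fit0 <- fit_prewhitened(Y, X)
  p <- t_contrast(fit0, c(ev = 1))$p
  band <- 1.96 * sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(mean(p < 0.05) - 0.05), band)
})

test_that("matched contrast modes agree on balanced noiseless designs", {
  blocks <- data.frame(onset = 15, duration = 180)
  onsets_e <- c(30, 80, 130)
  onsets_c <- c(55, 105, 155)
  ev_pool <- data.frame(onset = c(onsets_e, onsets_c), duration = 0,
                        regressor = rep(c("error", "control"), each = 3))
  ev_pair <- data.frame(onset = c(rbind(onsets_e, onsets_c)), duration = 0,
                        regressor = as.vector(t(outer(
                          c("error_", "control_"), 1:3, paste0))))
  spec <- bold_gen_spec(n_scans = 90,
                        betas = c(block = 0.5, go = 0, error = 2,
                                  control = 1),
                        sd = 0, drift_amplitude = 0)
  sim <- gen_bold(ev_pool, blocks, spec)
  acq <- sim$acq
  fit_pool <- fit_prewhitened(sim$Y, build_design(ev_pool, blocks, acq))
  # identical event trains under per-pair naming
  spec2 <- bold_gen_spec(n_scans = 90,
                         betas = c(block = 0.5, go = 0,
                                   error_1 = 2, error_2 = 2, error_3 = 2,
                                   control_1 = 1, control_2 = 1,
                                   control_3 = 1),
                         sd = 0, drift_amplitude = 0)
  sim2 <- gen_bold(ev_pair, blocks, spec2)
  fit_pair <- fit_prewhitened(sim2$Y, build_design(ev_pair, blocks, acq))
  mc_pool <- matched_contrast(fit_pool)
  mc_pair <- matched_contrast(fit_pair)
  expect_equal(mc_pool$mode, "pooled")
  expect_equal(mc_pair$mode, "per_pair")
  expect_equal(mc_pool$value, 1, tolerance = 0.02)
  expect_equal(mc_pair$value, mc_pool$value, tolerance = 0.02)

  # identical error and control event trains give a zero contrast
  ev_same <- data.frame(onset = rep(onsets_e, 2), duration = 0,
                        regressor = rep(c("error", "control"), each = 3))
  spec0 <- bold_gen_spec(n_scans = 90,
                         betas = c(block = 0.5, go = 0, error = 1,
                                   control = 1),
                         sd = 0, drift_amplitude = 0)
  sim0 <- gen_bold(ev_same, blocks, spec0)
  des0 <- build_design(ev_same, blocks, acq)
  # identical trains make error/control columns collinear by construction
  expect_error(fit_prewhitened(sim0$Y, des0), "collinear")
})

test_that("sphere ROI values match the brute-force voxel oracle", {
  dims <- c(15L, 15L, 15L)
  set.seed(8)
  map <- array(rnorm(prod(dims)), dims)
  vox <- c(3, 3, 3)
  org <- c(-21, -21, -21)
  for (cases in list(list(c(0, 0, 0), 6), list(c(1.5, -2, 4), 6),
                     list(c(0, 0, 0), 4), list(c(6, 5, 4), 5))) {
    roi <- roi_spec(cases[[1]], cases[[2]])
    idx <- sphere_roi_indices(dims, roi, vox, org)
    expect_equal(length(idx),
                 oracle_sphere_count(dims, roi$center, roi$radius, vox, org))
    expect_equal(sphere_roi_values(map, roi, vox, org), mean(map[idx]))
  }
  # radius -> 0+ picks the single nearest voxel (center on a voxel center)
  roi1 <- roi_spec(c(0, 0, 0), 0.1)
  expect_equal(length(sphere_roi_indices(dims, roi1, vox, org)), 1L)
  # uniform map returns the uniform value
  umap <- array(7, dims)
  expect_equal(sphere_roi_values(umap, roi_spec(c(0, 0, 0), 6), vox, org), 7)
  # empty intersection is absent with a diagnostic
  far <- roi_spec(c(999, 0, 0), 2)
  expect_warning(v <- sphere_roi_values(map, far, vox, org), "no voxel")
  expect_true(is.na(v))
})

test_that("second level: Bonferroni family and noncentral-t power", {
  # all-zero inputs give t = 0 everywhere
  z <- matrix(0, 10, 3)
  sl <- second_level(z)
  expect_true(all(sl$table$t == 0))

  # 25 ROIs at alpha 0.05: per-ROI threshold 0.002
  v25 <- matrix(rnorm(20 * 25), 20, 25)
  sl25 <- second_level(v25)
  expect_equal(sl25$p_threshold, 0.002)

  # empirical power at delta/sigma = 1, n = 20 matches the closed form
  set.seed(10)
  reps <- 4000; n <- 20
  X <- matrix(rnorm(n * reps, mean = 1), n, reps)
  m <- colMeans(X)
  se <- sqrt((colSums(X^2) - n * m^2) / (n - 1)) / sqrt(n)
  p <- 2 * stats::pt(-abs(m / se), n - 1)
  power_hat <- mean(p < 0.05)
  power_true <- oracle_t_power(1, n)
  mc_se <- sqrt(power_true * (1 - power_true) / reps)
  expect_lt(abs(power_hat - power_true), 3 * mc_se)
})

test_that("high-pass DCT columns absorb slow drift without biasing events", {
  n <- 150
  acq <- acquisition_spec(TR = TR, n_scans = n)
  blocks <- data.frame(onset = c(20, 150, 280), duration = 80)
  events <- data.frame(onset = c(40, 60, 170, 190, 300, 320), duration = 0,
                       regressor = "ev")
  spec <- bold_gen_spec(n_scans = n, betas = c(block = 1, go = 0.3, ev = 1),
                        sd = 0, drift_amplitude = 3, drift_period = 256)
  sim <- gen_bold(events, blocks, spec, seed = 4)
  fit <- fit_prewhitened(sim$Y, build_design(events, blocks, acq))
  expect_lt(abs(fit$beta["ev", 1] - 1), 0.01)
})

test_that("mixed design separates sustained from transient activity", {
  # omitting the block boxcar inflates event-beta bias; the full model
  # recovers both amplitudes
  n <- 150
  acq <- acquisition_spec(TR = TR, n_scans = n)
  blocks <- data.frame(onset = c(20, 150, 280), duration = 80)
  events <- data.frame(onset = as.vector(outer(c(15, 30, 45, 60),
                                               blocks$onset, "+")),
                       duration = 0, regressor = "ev")
  spec <- bold_gen_spec(n_scans = n, betas = c(block = 2, go = 0, ev = 1),
                        sd = 0, drift_amplitude = 0)
  sim <- gen_bold(events, blocks, spec)
  full <- fit_prewhitened(sim$Y, build_design(events, blocks, acq))
  expect_lt(abs(full$beta["ev", 1] - 1), 0.02)
  expect_lt(abs(full$beta["block", 1] - 2), 0.02)
  # drop the boxcar: the event beta soaks up sustained activity
  full_des <- build_design(events, blocks, acq)
  Xr <- full_des$X[, setdiff(colnames(full_des$X), c("block", "go")),
                   drop = FALSE]
  red <- fit_prewhitened(sim$Y, Xr)
  expect_gt(abs(red$beta["ev", 1] - 1), 0.2)
})
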