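test_that("IAF-anchored bands instantiate correctly and reject out-of-range input", {
  b10 <- bands_from_iaf(10)
  expect_equal(b10$theta, c(4, 8))
  expect_equal(b10$alpha, c(8, 12))
  expect_equal(b10$beta, c(12, 26))
  b8 <- bands_from_iaf(8)
  expect_equal(b8$theta, c(2, 6))
  expect_equal(b8$alpha, c(6, 10))
  expect_equal(b8$beta, c(10, 24))
  expect_error(bands_from_iaf(6), "7")
  expect_error(bands_from_iaf(13.5), "7")
})

test_that("IAF estimation recovers the configured alpha peak and falls back on 1/f", {
  for (f_alpha in c(10, 8.5)) {
    sim <- simulate_dyad(dyad_scenario(
      phases = data.frame(label = "eyes_closed", duration_s = 60),
      iaf_1 = f_alpha, iaf_2 = f_alpha, phase_coupling = 0, seed = 17))
    expect_equal(estimate_iaf(sim$session$rec1), f_alpha, tolerance = 0.5)
  }
  # pure 1/f noise: no alpha peak -> documented 10 Hz fallback with warning
  set.seed(18)
  fs <- 125
  n <- 60 * fs
  noisy <- t(sapply(1:3, function(i) cumsum(rnorm(n)) / 30))
  rec <- eeg_recording(noisy, fs, c("P3", "Pz", "P4"))
  expect_warning(iaf <- estimate_iaf(rec), "falling back")
  expect_identical(iaf, 10)
  short <- eeg_recording(noisy[, 1:(10 * fs)], fs, c("P3", "Pz", "P4"))
  expect_error(estimate_iaf(short), "too short")
})

test_that("GFP of a band-centre sinusoid is A^2/2 and scales quadratically", {
  ep <- make_epochs("Pz", 10, list(3), n_epochs = 10)
  g <- gfp(ep, c(8, 12), "Pz")
  expect_equal(mean(g), 3^2 / 2, tolerance = 0.05 * 3^2 / 2)
  ep2 <- make_epochs("Pz", 10, list(6), n_epochs = 10)
  g2 <- gfp(ep2, c(8, 12), "Pz")
  expect_equal(g2$values, 4 * g$values, tolerance = 1e-8)
  expect_true(all(g$values[g$valid_mask] >= 0))
})

test_that("windows dominated by artifacts are invalid without contaminating neighbours", {
  ep <- make_epochs("Pz", 10, list(3), n_epochs = 10)
  ep$artifact_mask[3:4] <- TRUE
  g <- gfp(ep, c(8, 12), "Pz", window_s = 2) # window 2 = epochs 3-4, fully artifactual
  expect_false(g$valid_mask[2])
  expect_true(all(g$valid_mask[-2]))
  g1 <- gfp(ep, c(8, 12), "Pz", window_s = 1)
  expect_identical(which(!g1$valid_mask), c(3L, 4L))
  expect_equal(g1$values[g1$valid_mask][1], 3^2 / 2, tolerance = 0.05 * 4.5)
})

test_that("workload index is the frontal-theta/parietal-alpha power ratio", {
  chans <- c("AF3", "AFz", "AF4", "P3", "Pz", "P4")
  # frontal channels carry 6 Hz theta amplitude 2sqrt2; parietal 10 Hz alpha amplitude 2
  ep <- make_epochs(chans, c(6, 6, 6, 10, 10, 10),
                    list(2 * sqrt(2), 2 * sqrt(2), 2 * sqrt(2), 2, 2, 2))
  W <- workload_index(ep, bands_from_iaf(10))
  expect_equal(mean(W), (8 / 2) / (4 / 2), tolerance = 0.05 * 2) # = 2
  # doubling frontal theta amplitude quadruples W
  ep2 <- make_epochs(chans, c(6, 6, 6, 10, 10, 10),
                     list(4 * sqrt(2), 4 * sqrt(2), 4 * sqrt(2), 2, 2, 2))
  W2 <- workload_index(ep2, bands_from_iaf(10))
  expect_equal(mean(W2) / mean(W), 4, tolerance = 0.01)
  # common rescaling of all channels leaves W unchanged
  ep3 <- ep
  ep3$epochs <- ep$epochs * 7
  W3 <- workload_index(ep3, bands_from_iaf(10))
  expect_equal(W3$values, W$values, tolerance = 1e-9)
  expect_error(workload_index(make_epochs("Pz", 10, list(1)), bands_from_iaf(10)),
               "needs channel")
})

test_that("approach-withdrawal index is AF4 minus AF3 alpha power, antisymmetric", {
  chans <- c("AF3", "AF4")
  ep <- make_epochs(chans, c(10, 10), list(sqrt(2), sqrt(6)))
  AW <- approach_withdrawal_index(ep, bands_from_iaf(10))
  expect_equal(mean(AW), 3 - 1, tolerance = 0.05 * 2)
  # identical signals -> 0
  ep0 <- make_epochs(chans, c(10, 10), list(2, 2))
  expect_equal(mean(approach_withdrawal_index(ep0, bands_from_iaf(10))), 0,
               tolerance = 1e-9)
  # swapping AF3 and AF4 flips the sign
  epsw <- make_epochs(c("AF4", "AF3"), c(10, 10), list(sqrt(2), sqrt(6)))
  AWsw <- approach_withdrawal_index(epsw, bands_from_iaf(10))
  expect_equal(AWsw$values, -AW$values, tolerance = 1e-9)
})

test_that("simulated workload and asymmetry profiles are recovered through the pipeline", {
  phases <- data.frame(label = c("low_diff", "high_diff", "cooperation"),
                       duration_s = c(30, 30, 30))
  sc <- dyad_scenario(
    phases = phases, phase_coupling = 0,
    workload_profile_1 = c(low_diff = 1, high_diff = 3, cooperation = 2),
    workload_profile_2 = c(low_diff = 1, high_diff = 3, cooperation = 2),
    asymmetry_profile_1 = c(low_diff = 1.5, high_diff = -1.5, cooperation = 1.5),
    asymmetry_profile_2 = c(low_diff = 1.5, high_diff = -1.5, cooperation = 1.5),
    w_log_sd = 0.05, aw_sd = 0.05, noise_rms_uV = 1, seed = 23)
  sim <- simulate_dyad(sc)
  ep <- preprocess_recording(sim$session$rec1)
  scheme <- bands_from_iaf(10)
  W <- workload_index(ep, scheme, window_s = 10)
  AW <- approach_withdrawal_index(ep, scheme, window_s = 10)
  ann <- sim$session$rec1$phase_annotations
  w_by_phase <- sapply(phases$label, function(p) mean(filter_phase(W, ann, p)))
  # rank order across the configured step profile {1, 3, 2} is exact
  expect_identical(order(w_by_phase), order(c(1, 3, 2)))
  aw_by_phase <- sapply(phases$label, function(p) mean(filter_phase(AW, ann, p)))
  # AW flips sign exactly where configured
  expect_identical(sign(aw_by_phase), c(low_diff = 1, high_diff = -1, cooperation = 1))
})
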